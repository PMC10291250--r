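#' Write a synthetic study to a CSV bundle
#'
#' Serializes every table of a [generate_study()] result to CSV files in
#' `out_dir` and writes a `manifest.json` recording the seed, the package
#' version, timestamps and the MD5 digest of every emitted file, so any
#' downstream output is traceable to its inputs.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for [generate_study()].
#' @return The `synthetic_study`, invisibly.
#' @export
run_simulate <- function(config = study_config(), out_dir, seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  study <- generate_study(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("metadata", "conduits", "flow", "geometry", "leaf_area",
              "ground_truth")
  paths <- file.path(out_dir, paste0(tables, ".csv"))
  for (i in seq_along(tables))
    utils::write.csv(study[[tables[i]]], paths[i], row.names = FALSE)
  manifest <- list(
    generator = paste0("xylemhydro ",
                       as.character(utils::packageVersion("xylemhydro"))),
    seed = seed,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_species = nrow(config$calibration),
    n_samples = nrow(study$metadata),
    files = as.list(tools::md5sum(paths)))
  names(manifest$files) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(study)
}

#' Read a CSV study bundle
#'
#' @param dir directory holding the bundle written by [run_simulate()] (the
#'   `ground_truth.csv` and `manifest.json` files are optional; a bundle of
#'   real measurements needs only the four measurement tables).
#' @return List of data frames (`metadata`, `conduits`, `flow`,
#'   `geometry`, `leaf_area`, and `ground_truth` when present).
#' @export
read_bundle <- function(dir) {
  need <- c("metadata", "conduits", "flow", "geometry", "leaf_area")
  out <- list()
  for (nm in need) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("bundle is missing ", basename(path))
    out[[nm]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) out$ground_truth <- utils::read.csv(gt)
  out
}

# assemble the long per-sample trait table from the three derivation steps
.sample_traits <- function(bundle) {
  anat <- derive_anatomy(bundle$conduits)
  hydr <- derive_hydraulics(bundle$flow, bundle$geometry, bundle$leaf_area)
  dens <- derive_density(bundle$geometry)
  meta <- bundle$metadata

  long_one <- function(df, cols) {
    rows <- lapply(names(cols), function(trait) {
      v <- df[[cols[[trait]]]]
      ok <- is.finite(v)
      if (!any(ok)) return(NULL)
      data.frame(sample_id = df$sample_id[ok], trait = trait,
                 value = v[ok], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  long <- rbind(
    long_one(anat, list(Dh = "Dh_um", CD = "CD_mm2", F = "F_pct",
                        KSpot = "KSpot_kg_m_MPa_s")),
    long_one(hydr, list(KShydr = "KShydr", KL = "KL", HV = "HV")),
    long_one(dens, list(WD = "WD_g_cm3")))
  m <- meta[, c("sample_id", "species", "leaf_habit", "tree_id", "organ",
                "height_m")]
  out <- merge(long, m, by = "sample_id")
  out$organ[out$organ == "stem_core"] <- "stem"
  out
}

# helper: contrast row as a data frame in the printed-table column layout
.contrast_row <- function(trait, organ, cr, transform) {
  data.frame(trait = trait, organ = organ, contrast = cr$contrast,
             SE = cr$SE, df = cr$df, t.ratio = cr$t_ratio,
             p.value = cr$p_value, transform = transform,
             stringsAsFactors = FALSE)
}

#' Analyze a study bundle
#'
#' Runs the full comparative analysis on a measurement bundle (a
#' `synthetic_study`, a list of tables, or a bundle directory): trait
#' derivation per sample, tree-wise averaging, species means, leaf-habit
#' contrasts (deciduous - evergreen, angiosperms only; conductivities on
#' the log10 scale with a back-transformed ratio column), organ contrasts
#' (root - branch on species means, raw scale, the printed-table
#' convention), Tukey letters per trait and organ across species,
#' the species-level Pearson correlation matrix, root-to-branch ratios
#' (tree-wise for KShydr and WD, species-wise otherwise) and
#' trait-height mixed models. With `out_dir` set, every result table is
#' written as CSV together with a manifest.
#'
#' @param bundle a `synthetic_study`, a list with the bundle tables, or a
#'   directory path for [read_bundle()].
#' @param out_dir optional output directory for CSV results.
#' @return An object of class `study_analysis`: list with `sample_traits`,
#'   `tree_means`, `species_means`, `habit_contrasts`, `organ_contrasts`,
#'   `letters`, `correlations`, `rb_ratios`, `height_models`, `wd_table`.
#' @export
run_analyze <- function(bundle, out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  long <- .sample_traits(bundle)

  samples <- long[, c("species", "tree_id", "organ", "leaf_habit", "trait",
                      "value")]
  tree_means <- aggregate_tree_means(samples)
  sp <- species_means(tree_means)
  log_traits <- c("KShydr", "KSpot", "KL")

  ## leaf-habit contrasts per trait x organ (angiosperm species means)
  ang <- sp[sp$leaf_habit %in% c("deciduous", "evergreen"), ]
  habit_rows <- list()
  for (tr in unique(ang$trait)) for (og in unique(ang$organ[ang$trait == tr])) {
    d <- ang[ang$trait == tr & ang$organ == og, ]
    if (length(unique(d$species)) < 4L) next
    if (min(table(d$leaf_habit)) < 2L || length(unique(d$leaf_habit)) < 2L)
      next
    v <- d$value
    tf <- "none"
    if (tr %in% log_traits) { v <- log10(v); tf <- "log10" }
    cr <- habit_contrast(v, d$leaf_habit)
    row <- .contrast_row(tr, og, cr, tf)
    row$ratio_dec_ev <- if (tf == "log10") 10^cr$contrast else NA_real_
    habit_rows[[paste(tr, og)]] <- row
  }
  habit_contrasts <- do.call(rbind, habit_rows)
  rownames(habit_contrasts) <- NULL

  ## organ contrasts root - branch (angiosperm species means, raw scale)
  organ_rows <- list()
  for (tr in c("Dh", "CD", "F", "KSpot", "KShydr", "WD")) {
    d <- ang[ang$trait == tr & ang$organ %in% c("root", "branch"), ]
    if (!all(c("root", "branch") %in% d$organ)) next
    cr <- organ_contrast(d$value, d$organ)
    organ_rows[[tr]] <- .contrast_row(tr, "root-branch", cr, "none")
  }
  organ_contrasts <- do.call(rbind, organ_rows)
  rownames(organ_contrasts) <- NULL

  ## Tukey letters across species, per trait x organ, on tree-level values
  letter_rows <- list()
  for (tr in c("Dh", "CD", "F", "KSpot", "KShydr", "WD")) {
    for (og in unique(tree_means$organ[tree_means$trait == tr])) {
      d <- tree_means[tree_means$trait == tr & tree_means$organ == og, ]
      if (length(unique(d$species)) < 2L || min(table(d$species)) < 2L) next
      v <- if (tr %in% log_traits) log10(d$value) else d$value
      ld <- tukey_letters(v, d$species)
      letter_rows[[paste(tr, og)]] <- data.frame(
        trait = tr, organ = og, species = names(ld$letters),
        letters = unname(ld$letters), stringsAsFactors = FALSE)
    }
  }
  letters_tab <- do.call(rbind, letter_rows)
  rownames(letters_tab) <- NULL

  ## species-level correlation matrix (log10 conductivities)
  sp_keyed <- sp
  sp_keyed$key <- paste0(sp_keyed$trait, "_", sp_keyed$organ)
  wide <- stats::reshape(
    sp_keyed[, c("species", "key", "value")],
    idvar = "species", timevar = "key", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  corr_traits <- intersect(
    c("Dh_root", "CD_root", "F_root", "KSpot_root", "KShydr_root",
      "Dh_branch", "CD_branch", "F_branch", "KSpot_branch", "KShydr_branch",
      "WD_root", "WD_branch", "WD_stem"), names(wide))
  wide_ang <- wide[wide$species %in% unique(ang$species), ]
  for (cl in intersect(as.vector(outer(log_traits, c("_root", "_branch"),
                                       paste0)),
                       names(wide_ang)))
    wide_ang[[cl]] <- log10(wide_ang[[cl]])
  correlations <- pearson_matrix(wide_ang, corr_traits)

  ## root-to-branch ratios: tree-wise for KShydr and WD, species-wise else
  rb_rows <- list()
  for (tr in c("Dh", "CD", "F", "KSpot", "KShydr", "WD")) {
    level <- if (tr %in% c("KShydr", "WD")) "tree" else "species"
    d <- if (level == "tree") tree_means else sp
    d <- d[d$trait == tr & d$organ %in% c("root", "branch"), ]
    unit <- if (level == "tree") "tree_id" else "species"
    w <- stats::reshape(d[, c(unit, "leaf_habit", "organ", "value")],
                        idvar = c(unit, "leaf_habit"), timevar = "organ",
                        direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    if (!all(c("root", "branch") %in% names(w))) next
    for (hb in unique(w$leaf_habit)) {
      wh <- w[w$leaf_habit == hb & is.finite(w$root) & is.finite(w$branch), ]
      if (nrow(wh) < 1L) next
      rb <- rb_ratio(wh$root, wh$branch)
      rb_rows[[paste(tr, hb)]] <- data.frame(
        trait = tr, leaf_habit = hb, level = level, n_pairs = rb$n,
        mean_ratio = rb$mean, stringsAsFactors = FALSE)
    }
  }
  rb_ratios <- do.call(rbind, rb_rows)
  rownames(rb_ratios) <- NULL

  ## trait-height mixed models (tree-level, angiosperms + gymnosperm)
  hm_rows <- list()
  for (tr in c("Dh", "KShydr")) for (og in c("root", "branch")) {
    d <- tree_means[tree_means$trait == tr & tree_means$organ == og, ]
    if (nrow(d) < 6L) next
    hts <- long[match(d$tree_id, long$tree_id), "height_m"]
    v <- if (tr %in% log_traits) log10(d$value) else d$value
    hm <- tryCatch(
      withCallingHandlers(
        height_model(v, hts, d$species),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(hm)) next
    hm_rows[[paste(tr, og)]] <- data.frame(
      trait = tr, organ = og, slope = hm$slope, slope_se = hm$slope_se,
      p.value = hm$p_value, method = hm$method,
      transform = if (tr %in% log_traits) "log10" else "none",
      stringsAsFactors = FALSE)
  }
  height_models <- do.call(rbind, hm_rows)
  rownames(height_models) <- NULL

  ## wood-density table: species x organ means with SE
  wd <- tree_means[tree_means$trait == "WD", ]
  wd_table <- stats::aggregate(value ~ species + leaf_habit + organ,
                               data = wd, FUN = mean)
  wd_se <- stats::aggregate(value ~ species + leaf_habit + organ, data = wd,
                            FUN = function(v) stats::sd(v) / sqrt(length(v)))
  names(wd_table)[names(wd_table) == "value"] <- "WD_mean"
  wd_table$WD_se <- wd_se$value[match(
    paste(wd_table$species, wd_table$organ),
    paste(wd_se$species, wd_se$organ))]

  out <- structure(list(
    sample_traits = long, tree_means = tree_means, species_means = sp,
    habit_contrasts = habit_contrasts, organ_contrasts = organ_contrasts,
    letters = letters_tab, correlations = correlations,
    rb_ratios = rb_ratios, height_models = height_models,
    wd_table = wd_table), class = "study_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(tree_means = tree_means, species_means = sp,
                  habit_contrasts = habit_contrasts,
                  organ_contrasts = organ_contrasts, letters = letters_tab,
                  rb_ratios = rb_ratios, height_models = height_models,
                  wood_density = wd_table)
    paths <- character(0)
    for (nm in names(files)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(files[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, "correlations.csv")
    utils::write.csv(
      data.frame(trait = rownames(correlations$r),
                 round(correlations$r, 4), check.names = FALSE), p,
      row.names = FALSE)
    paths <- c(paths, p)
    manifest <- list(
      analyzer = paste0("xylemhydro ",
                        as.character(utils::packageVersion("xylemhydro"))),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      files = as.list(tools::md5sum(paths)))
    names(manifest$files) <- basename(paths)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis:", length(unique(x$species_means$species)),
      "species\n\nOrgan contrasts (root - branch, species means):\n")
  print(x$organ_contrasts, digits = 3)
  cat("\nLeaf-habit contrasts (deciduous - evergreen):\n")
  print(x$habit_contrasts[, c("trait", "organ", "contrast", "SE", "df",
                              "t.ratio", "p.value", "transform")],
        digits = 3)
  invisible(x)
}
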