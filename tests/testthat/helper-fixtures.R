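# Shared fixtures: small configurations and convenience constructors used
# across the test files. Everything is generated in code; no data files.

# a reduced study configuration (4 species, 2 trees) for fast structural
# tests; statistical calibration tests use the full default config instead
small_config <- function(n_trees = 2L, ...) {
  cal <- species_calibration()
  cal <- cal[cal$species %in% c("Albizia schimperiana", "Croton macrostachyus",
                                "Chionanthus mildbraedii",
                                "Ekebergia capensis"), ]
  study_config(calibration = cal, n_trees = n_trees, ...)
}

# a deterministic conduit set with the given diameters
cs_of <- function(diameters, sector_area = NULL, organ = "root",
                  angle = 45) {
  if (is.null(sector_area)) sector_area <- 4 * sum(pi * diameters^2 / 4)
  conduit_set("fix", organ, sector_angle = angle, sector_area = sector_area,
              lumen_diameters = diameters)
}

# pooled two-sample t computation, written independently of the package's
# linear-model route; serves as the oracle for the contrast operations
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  est <- mean(x) - mean(y)
  t <- est / se
  list(estimate = est, se = se, df = nx + ny - 2, t = t,
       p = 2 * pt(abs(t), nx + ny - 2, lower.tail = FALSE))
}
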