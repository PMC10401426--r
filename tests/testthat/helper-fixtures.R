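# Fixture builders and independent oracles shared across test files.

# O(n^2) brute-force neighbor counts via a full distance matrix --
# deliberately a different code path from the package's grid index.
brute_flag_counts <- function(cells, flags, radius) {
  n <- nrow(cells)
  if (!n) return(matrix(0, 0, length(flags), dimnames = list(NULL, flags)))
  D <- as.matrix(stats::dist(cells[, c("x", "y")]))
  A <- (D <= radius)
  diag(A) <- FALSE
  out <- vapply(flags, function(f)
    as.vector(A %*% as.numeric(!is.na(cells[[f]]) & cells[[f]])),
    numeric(n))
  matrix(out, nrow = n, dimnames = list(cells$cell_id, flags))
}

# Uniform random core on a square with independent Bernoulli flags.
random_core <- function(n, width = 600, p = c(CD3 = 0.3, CD8 = 0.15,
                                              NKp46 = 0.1, MHC1 = 0.4),
                        core_id = "rc1", patient_id = "rp1") {
  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                      x = runif(n, 0, width), y = runif(n, 0, width),
                      stringsAsFactors = FALSE)
  for (f in names(p)) cells[[f]] <- runif(n) < p[[f]]
  core_table(cells, core_id, patient_id, area_um2 = width^2)
}

# Hand-buildable core from explicit coordinates and flags.
toy_core <- function(x, y, ..., area_um2 = 1e6, core_id = "toy",
                     patient_id = "tp") {
  cells <- data.frame(cell_id = sprintf("t%02d", seq_along(x)), x = x, y = y,
                      stringsAsFactors = FALSE)
  flags <- list(...)
  for (f in names(flags)) cells[[f]] <- flags[[f]]
  core_table(cells, core_id, patient_id, area_um2 = area_um2)
}

# Small-world point-process config: same cluster geometry as the default
# stated world, quarter-radius core, used where many replicates are needed.
small_world <- function() {
  point_process_config(
    core_radius = 200,
    background_rate = c(CD3 = 1e-3, CD8 = 0, NK = 2e-5),
    clusters = list(CD3 = cluster_spec(8 / (pi * 200^2), 30, 15, 0.8),
                    CD8 = cluster_spec(4 / (pi * 200^2), 60, 12, 0.95),
                    NK = cluster_spec(6 / (pi * 200^2), 15, 8, 0)),
    tumor_rate = 1e-3, mhc1_discs = 2, mhc1_disc_radius = 60)
}

# Clinical table for cohort-summary worked examples: n patients, k of whom
# sit in the named level of a two-level factor.
clinical_with_counts <- function(n, k, field = "metastasis_event") {
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   followup_months = rep(12, n), stringsAsFactors = FALSE)
  df[[field]] <- c(rep(TRUE, k), rep(FALSE, n - k))
  df
}

km_median <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (!length(i)) Inf else curve$time[min(i)]
}
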