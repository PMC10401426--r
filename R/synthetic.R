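## Synthetic-data generators.
##
## The spatial generator is a marked point process on a circular TMA core:
## homogeneous Poisson background per phenotype plus Neyman-Scott (Thomas)
## clusters -- Poisson parents, Poisson(mu) offspring displaced by an
## isotropic Gaussian(sigma), offspring outside the core disc rejected.
## Tumor cells carry an MHC-I flag inside disc-shaped MHC-I-positive
## fields; immune phenotypes are MHC-I-agnostic (flag NA). Cluster
## parents can be biased into the MHC-I fields (mhc1_affinity), which is
## how T-cell aggregates co-localized with MHC-I-positive regions are
## emulated, and phenotype pairs can share cluster parents
## (cross_attraction) to dial co-aggregation from full segregation (0)
## to full sharing (1).
##
## Default rates describe a sparsely infiltrated sarcoma-like core and
## are calibrated only to reproduce the qualitative ordering of in-range
## counts (dense CD8 self-aggregates > diffuse CD3 > NK micro-clusters >
## T cells around NK centers), not any printed values.

#' Thomas-cluster component specification
#'
#' @param parent_rate parents per square micrometre.
#' @param mean_offspring mean offspring per parent (Poisson).
#' @param offspring_sd isotropic Gaussian displacement SD, micrometres.
#' @param mhc1_affinity fraction in `[0, 1]` of parents placed uniformly
#'   inside the MHC-I-positive discs instead of the whole core.
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(parent_rate, mean_offspring, offspring_sd,
                         mhc1_affinity = 0) {
  if (parent_rate < 0 || mean_offspring < 0) stopf("cluster rates must be >= 0")
  if (offspring_sd <= 0) stopf("offspring_sd must be > 0")
  if (mhc1_affinity < 0 || mhc1_affinity > 1)
    stopf("mhc1_affinity must lie in [0, 1]")
  structure(list(parent_rate = parent_rate, mean_offspring = mean_offspring,
                 offspring_sd = offspring_sd, mhc1_affinity = mhc1_affinity),
            class = "cluster_spec")
}

#' Point-process configuration for one synthetic core
#'
#' Defaults describe the stated world of the downstream analyses: a
#' 500-um-radius circular core; a tumor-cell field with three 120-um
#' MHC-I-positive discs; dense CD8 aggregates and moderate CD3 aggregates
#' preferentially inside the MHC-I discs over a diffuse CD3 background;
#' NK micro-aggregates placed independently of the discs and of the T
#' cells (full NK/T segregation: no shared parents).
#'
#' @param core_radius disc radius, micrometres.
#' @param background_rate named nonnegative vector, phenotype ->
#'   homogeneous Poisson intensity (cells per square micrometre).
#'   Phenotypes: `"CD3"` (CD3+CD8- T), `"CD8"` (CD3+CD8+ T), `"NK"`
#'   (NKp46+CD56+).
#' @param clusters named list of [cluster_spec()] per phenotype.
#' @param cross_attraction named list, `"A|B"` -> fraction in `[0, 1]` of
#'   phenotype B's cluster parents copied from phenotype A's parents.
#' @param tumor_rate tumor-cell Poisson intensity (cells per square
#'   micrometre).
#' @param mhc1_discs either a count (discs drawn uniformly inside the
#'   core at simulation time) or an explicit list of
#'   `list(center = c(x, y), radius = r)`.
#' @param mhc1_disc_radius disc radius used when `mhc1_discs` is a count.
#' @param seed default seed recorded with the config.
#' @return a `point_process_config` list.
#' @export
point_process_config <- function(core_radius = 500,
                                 background_rate = c(CD3 = 1e-3, CD8 = 0,
                                                     NK = 2e-5),
                                 clusters = list(
                                   CD3 = cluster_spec(8 / (pi * 500^2), 30, 15, 0.8),
                                   CD8 = cluster_spec(4 / (pi * 500^2), 60, 12, 0.95),
                                   NK = cluster_spec(6 / (pi * 500^2), 15, 8, 0)),
                                 cross_attraction = list(),
                                 tumor_rate = 3e-3,
                                 mhc1_discs = 3, mhc1_disc_radius = 120,
                                 seed = 1L) {
  if (!is_scalar_num(core_radius) || core_radius <= 0)
    stopf("core_radius must be a positive number")
  if (any(background_rate < 0) || tumor_rate < 0)
    stopf("intensities must be >= 0")
  for (cs in clusters)
    if (!inherits(cs, "cluster_spec")) stopf("clusters must be cluster_spec")
  for (f in cross_attraction)
    if (f < 0 || f > 1) stopf("shared-parent fractions must lie in [0, 1]")
  structure(list(core_radius = core_radius, background_rate = background_rate,
                 clusters = clusters, cross_attraction = cross_attraction,
                 tumor_rate = tumor_rate, mhc1_discs = mhc1_discs,
                 mhc1_disc_radius = mhc1_disc_radius, seed = seed),
            class = "point_process_config")
}

runif_disc <- function(n, radius, center = c(0, 0)) {
  r <- radius * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

in_any_disc <- function(x, y, discs) {
  inside <- rep(FALSE, length(x))
  for (d in discs)
    inside <- inside |
      ((x - d$center[1])^2 + (y - d$center[2])^2 <= d$radius^2)
  inside
}

#' Simulate one TMA core
#'
#' @param config a [point_process_config()].
#' @param seed integer seed (defaults to the config's); identical
#'   config+seed yields identical output.
#' @param core_id,patient_id identifiers stamped on the result.
#' @return a [core_table] whose cells carry a primary `phenotype` label
#'   (`tumor`/`CD3`/`CD8`/`NK`), panel flags (CD8 implies CD3; NK cells
#'   are NKp46+CD56+), and an `MHC1` flag defined on tumor cells only.
#' @export
simulate_core <- function(config, seed = config$seed, core_id = "core1",
                          patient_id = "p1") {
  stopifnot(inherits(config, "point_process_config"))
  if (!is.null(seed)) set.seed(seed)
  R <- config$core_radius
  A <- pi * R^2

  discs <- config$mhc1_discs
  if (is.numeric(discs)) {
    nd <- discs
    discs <- lapply(seq_len(nd), function(i) {
      ctr <- runif_disc(1, max(R - config$mhc1_disc_radius, 0))
      list(center = as.numeric(ctr), radius = config$mhc1_disc_radius)
    })
  }

  pts <- list()
  add <- function(xy, phenotype) {
    if (nrow(xy)) pts[[length(pts) + 1L]] <<-
        data.frame(x = xy[, 1], y = xy[, 2], phenotype = phenotype,
                   stringsAsFactors = FALSE)
  }

  # tumor field
  add(runif_disc(stats::rpois(1, config$tumor_rate * A), R), "tumor")

  # immune phenotypes: background + Thomas clusters. Parents are drawn
  # for every phenotype first, then cross-attraction replaces a fraction
  # of the attracted phenotype's parents with shared ones, so sharing
  # does not depend on the order phenotypes are listed in the config.
  phenos <- union(names(config$background_rate), names(config$clusters))
  parents <- list()
  for (ph in phenos) {
    lam <- config$background_rate[[ph]] %||% 0
    add(runif_disc(stats::rpois(1, lam * A), R), ph)
    cs <- config$clusters[[ph]]
    if (is.null(cs)) next
    np <- stats::rpois(1, cs$parent_rate * A)
    par_xy <- runif_disc(np, R)
    if (np && cs$mhc1_affinity > 0 && length(discs)) {
      move <- stats::runif(np) < cs$mhc1_affinity
      if (any(move)) {
        which_disc <- sample.int(length(discs), sum(move), replace = TRUE)
        for (i in seq_along(which_disc)) {
          d <- discs[[which_disc[i]]]
          par_xy[which(move)[i], ] <- runif_disc(1, d$radius, d$center)
        }
      }
    }
    parents[[ph]] <- par_xy
  }
  for (key in names(config$cross_attraction)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(ab) != 2 || !all(ab %in% names(parents)))
      stopf("cross_attraction key '%s' must name two clustered phenotypes",
            key)
    src <- parents[[ab[1]]]; dst <- parents[[ab[2]]]
    if (!nrow(src) || !nrow(dst)) next
    share <- stats::runif(nrow(dst)) < config$cross_attraction[[key]]
    if (any(share))
      dst[share, ] <- src[sample.int(nrow(src), sum(share), replace = TRUE),
                          , drop = FALSE]
    parents[[ab[2]]] <- dst
  }
  for (ph in names(parents)) {
    cs <- config$clusters[[ph]]
    par_xy <- parents[[ph]]
    np <- nrow(par_xy)
    if (!np) next
    n_off <- stats::rpois(np, cs$mean_offspring)
    tot <- sum(n_off)
    if (tot) {
      off <- cbind(rep(par_xy[, 1], n_off) + stats::rnorm(tot, 0, cs$offspring_sd),
                   rep(par_xy[, 2], n_off) + stats::rnorm(tot, 0, cs$offspring_sd))
      off <- off[off[, 1]^2 + off[, 2]^2 <= R^2, , drop = FALSE]
      add(off, ph)
    }
  }

  cells <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(), y = numeric(), phenotype = character(),
               stringsAsFactors = FALSE)
  n <- nrow(cells)
  cells$cell_id <- sprintf("%s_%05d", core_id, seq_len(n))
  cells$CD3 <- cells$phenotype %in% c("CD3", "CD8")
  cells$CD8 <- cells$phenotype == "CD8"
  cells$NKp46 <- cells$phenotype == "NK"
  cells$CD56 <- cells$phenotype == "NK"
  cells$MHC1 <- ifelse(cells$phenotype == "tumor",
                       in_any_disc(cells$x, cells$y, discs), NA)
  core_table(cells[, c("cell_id", "x", "y", "phenotype", cell_panel())],
             core_id = core_id, patient_id = patient_id,
             area_um2 = A, geometry = list(center = c(0, 0), radius = R),
             provenance = sprintf("synthetic (seed %s)",
                                  seed %||% "inherited"))
}

#' Cohort configuration for survival simulation
#'
#' Event times follow an exponential proportional-hazards model on
#' standardized per-patient marker scores:
#' `rate_i = baseline_rate * exp(sum_m beta_m * z_im)` where `z_im` is the
#' cohort z-score of patient i's marker-m density. Metastasis and death
#' are independent exponentials on the same linear predictor (metastasis
#' at `met_rate_multiplier` times the baseline); censoring is an
#' independent exponential truncated at the follow-up horizon.
#'
#' @param n_patients cohort size, >= 2.
#' @param cores_per_patient replicate cores per patient (TMA designs
#'   typically place 3 consecutive-section cores).
#' @param baseline_rate events per month.
#' @param hazard_coefs named numeric, `<flag>` -> log-hazard per SD of
#'   that marker's density (e.g. `c(NKp46 = -0.5)`).
#' @param met_rate_multiplier metastasis baseline relative to death.
#' @param censor_rate censoring events per month.
#' @param horizon_months administrative censoring horizon.
#' @param surgery_offset_months surgery time after diagnosis.
#' @param seed integer.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 12, cores_per_patient = 3,
                          baseline_rate = 0.02,
                          hazard_coefs = c(NKp46 = -0.5),
                          met_rate_multiplier = 1.5,
                          censor_rate = 0.015, horizon_months = 60,
                          surgery_offset_months = 1, seed = 1L) {
  if (!is_count(n_patients) || n_patients < 2) stopf("n_patients must be >= 2")
  if (!is_count(cores_per_patient) || cores_per_patient < 1)
    stopf("cores_per_patient must be >= 1")
  if (baseline_rate <= 0 || censor_rate <= 0 || met_rate_multiplier <= 0)
    stopf("rates must be > 0")
  if (!is_scalar_num(horizon_months) || horizon_months <= 0)
    stopf("follow-up horizon must be > 0")
  structure(list(n_patients = n_patients,
                 cores_per_patient = cores_per_patient,
                 baseline_rate = baseline_rate, hazard_coefs = hazard_coefs,
                 met_rate_multiplier = met_rate_multiplier,
                 censor_rate = censor_rate, horizon_months = horizon_months,
                 surgery_offset_months = surgery_offset_months, seed = seed),
            class = "cohort_config")
}

## Table-1-like categorical worlds for the clinical covariates.
sample_covariates <- function(n) {
  data.frame(
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.408, 0.592)),
    treatment_group = sample(treatment_groups(), n, TRUE,
                             prob = c(0.269, 0.554, 0.038, 0.139)),
    histology = sample(c("UPS", "liposarcoma", "myxofibrosarcoma",
                         "synovial", "leiomyosarcoma", "other"), n, TRUE,
                       prob = c(0.277, 0.215, 0.192, 0.100, 0.077, 0.139)),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort: cores, marker scores, and survival
#'
#' @param config a [cohort_config()].
#' @param spatial_config a [point_process_config()] used for every core.
#' @return list: `cores` (flat list of [core_table]), `clinical`
#'   (data.frame in the [read_clinical_table()] schema), `scores`
#'   (per-patient marker densities and their z-scores), `truth` (the
#'   generating parameters, for recovery assertions).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            spatial_config = point_process_config()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(spatial_config, "point_process_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$n_patients
  pids <- sprintf("P%03d", seq_len(np))
  cores <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(config$cores_per_patient)) {
      cid <- sprintf("%s_core%d", pids[i], j)
      cores[[cid]] <- simulate_core(spatial_config, seed = NULL,
                                    core_id = cid, patient_id = pids[i])
    }
  }

  markers <- names(config$hazard_coefs)
  score_df <- NULL
  lp <- rep(0, np)
  for (m in markers) {
    sc <- marker_scores(cores, m, "density_per_mm2")
    sc <- sc[match(pids, sc$patient_id), ]
    z <- if (stats::sd(sc$value) > 0)
      (sc$value - mean(sc$value)) / stats::sd(sc$value) else rep(0, np)
    lp <- lp + config$hazard_coefs[[m]] * z
    score_df <- rbind(score_df,
                      data.frame(patient_id = pids, marker = m,
                                 kind = "density_per_mm2", value = sc$value,
                                 z = z, stringsAsFactors = FALSE))
  }

  rate <- config$baseline_rate * exp(lp)
  t_death <- stats::rexp(np, rate)
  t_met <- stats::rexp(np, rate * config$met_rate_multiplier)
  t_cens <- pmin(stats::rexp(np, config$censor_rate), config$horizon_months)
  off <- config$surgery_offset_months

  death_event <- t_death <= t_cens
  met_event <- t_met <= pmin(t_death, t_cens)
  clinical <- cbind(
    data.frame(patient_id = pids,
               surgery_offset_months = off,
               followup_months = off + pmin(t_death, t_cens),
               death_months = ifelse(death_event, off + t_death, NA),
               death_event = death_event,
               metastasis_months = ifelse(met_event, off + t_met, NA),
               metastasis_event = met_event,
               stringsAsFactors = FALSE),
    sample_covariates(np))

  list(cores = cores, clinical = clinical, scores = score_df,
       truth = list(baseline_rate = config$baseline_rate,
                    hazard_coefs = config$hazard_coefs,
                    met_rate_multiplier = config$met_rate_multiplier,
                    linear_predictor = stats::setNames(lp, pids),
                    seed = config$seed))
}

#' Simulate per-core IHC intensity-bin fractions
#'
#' Draws each core's `(f0, f1, f2, f3)` from a Dirichlet distribution
#' (independent gammas, normalised). A zero weight pins that bin to
#' exactly 0; the default weights describe the low-expression regime of
#' immune IHC markers in sarcoma (most cells unstained).
#'
#' @param n_cores number of cores.
#' @param dirichlet_weights 4 nonnegative weights for bins 0/1+/2+/3+,
#'   not all zero.
#' @param seed integer.
#' @return data.frame with columns `f0..f3`, rows summing to 1.
#' @export
simulate_ihc_bins <- function(n_cores, dirichlet_weights = c(8, 1.5, 0.4, 0.1),
                              seed = 1L) {
  if (length(dirichlet_weights) != 4 || any(dirichlet_weights < 0))
    stopf("dirichlet_weights must be 4 nonnegative values")
  if (sum(dirichlet_weights) == 0) stopf("dirichlet_weights must not all be zero")
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(dirichlet_weights, function(w)
    if (w > 0) stats::rgamma(n_cores, shape = w) else rep(0, n_cores),
    numeric(n_cores))
  g <- matrix(g, nrow = n_cores)
  out <- as.data.frame(g / rowSums(g))
  names(out) <- c("f0", "f1", "f2", "f3")
  out
}
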