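test_that("index queries on an empty core return nothing", {
  tb <- core_table(data.frame(cell_id = character(), x = numeric(),
                              y = numeric()), "k", "p", area_um2 = 1)
  idx <- build_index(tb)
  expect_identical(query_index(idx, 0, 0, 1e6), integer())
})

test_that("grid index agrees with exhaustive search on random queries", {
  set.seed(101)
  tb <- random_core(1000, width = 500)
  idx <- build_index(tb, bin = 30)
  for (q in 1:50) {
    px <- runif(1, -50, 550); py <- runif(1, -50, 550)
    d2 <- (tb$cells$x - px)^2 + (tb$cells$y - py)^2
    want <- sort(which(d2 <= 30^2))
    expect_identical(sort(query_index(idx, px, py, 30)), want)
  }
  # index supports radii different from its bin size
  px <- 250; py <- 250
  for (r in c(5, 75, 400)) {
    d2 <- (tb$cells$x - px)^2 + (tb$cells$y - py)^2
    expect_identical(sort(query_index(idx, px, py, r)),
                     sort(which(d2 <= r^2)))
  }
})

test_that("duplicate coordinates: both cells returned, and they are mutual neighbors", {
  tb <- toy_core(c(10, 10, 90), c(10, 10, 90), NKp46 = c(TRUE, TRUE, TRUE))
  idx <- build_index(tb)
  expect_length(query_index(idx, 10, 10, 1), 2)
  nc <- neighbor_counts(tb, "NKp46", "NKp46", radius = 30)
  expect_equal(nc$per_center$NKp46, c(1, 1, 0))
})

test_that("self-exclusion and inclusive 30 um boundary", {
  solo <- toy_core(5, 5, NKp46 = TRUE)
  expect_equal(neighbor_counts(solo, "NKp46", "NKp46")$per_center$NKp46, 0)
  pair <- toy_core(c(0, 30), c(0, 0), CD3 = c(TRUE, TRUE))
  expect_equal(neighbor_counts(pair, "CD3", "CD3", radius = 30)$per_center$CD3,
               c(1, 1))
  # just outside the closed disc
  pair2 <- toy_core(c(0, 30.0001), c(0, 0), CD3 = c(TRUE, TRUE))
  expect_equal(neighbor_counts(pair2, "CD3", "CD3", 30)$per_center$CD3, c(0, 0))
})

test_that("neighbor counts equal the O(n^2) oracle on a 200-cell fixture", {
  set.seed(102)
  tb <- random_core(200, width = 300)
  flags <- c("CD3", "CD8", "NKp46")
  want <- brute_flag_counts(tb$cells, flags, 30)
  for (ctr in flags) {
    nc <- neighbor_counts(tb, ctr, flags, 30)
    keep <- tb$cells[[ctr]]
    for (tg in flags)
      expect_equal(nc$per_center[[tg]], unname(want[keep, tg]))
  }
  expect_error(neighbor_counts(tb, "CD99", "CD3"), "unknown phenotype")
})

test_that("clustering matrix matches manual enumeration on a 6-cell core", {
  # A,B: NK pair 10 um apart; C,D (CD3) and E (CD8, hence CD3) mutually
  # within 30 um; F: isolated NK
  tb <- toy_core(x = c(0, 10, 100, 110, 105, 300),
                 y = c(0, 0, 0, 0, 10, 300),
                 CD3 = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                 CD8 = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                 NKp46 = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  cm <- clustering_matrix(tb, c("CD3", "CD8", "NKp46"), 30)
  want <- rbind(CD3 = c(2, 2 / 3, 0),
                CD8 = c(2, 0, 0),
                NKp46 = c(0, 0, 2 / 3))
  dimnames(want) <- list(c("CD3", "CD8", "NKp46"), c("CD3", "CD8", "NKp46"))
  expect_equal(cm$pooled, want)
  expect_equal(cm$patient_mean, want)  # single core, single patient
})

test_that("a phenotype absent from all cores yields NA rows, not zero", {
  tb <- toy_core(c(0, 10), c(0, 0), CD3 = c(TRUE, TRUE),
                 NKp46 = c(FALSE, FALSE))
  cm <- clustering_matrix(tb, c("CD3", "NKp46"), 30)
  expect_true(all(is.na(cm$pooled["NKp46", ])))
  expect_false(anyNA(cm$pooled["CD3", ]))
  expect_equal(cm$report$center_type, "NKp46")
})

test_that("pair-symmetry identity holds on random fixtures", {
  set.seed(103)
  for (i in 1:5) {
    tb <- random_core(300, width = 400)
    cm <- clustering_matrix(tb, c("CD3", "NKp46"), 30)
    lng <- cm$per_center
    s_ab <- sum(lng$count[lng$center_type == "CD3" & lng$target_type == "NKp46"])
    s_ba <- sum(lng$count[lng$center_type == "NKp46" & lng$target_type == "CD3"])
    expect_equal(s_ab, s_ba)
    # same-type totals are twice the number of unordered in-range pairs
    s_aa <- sum(lng$count[lng$center_type == "CD3" & lng$target_type == "CD3"])
    D <- as.matrix(dist(tb$cells[, c("x", "y")]))
    cd3 <- which(tb$cells$CD3)
    pairs <- sum(D[cd3, cd3][upper.tri(D[cd3, cd3])] <= 30)
    expect_equal(s_aa, 2 * pairs)
  }
})

test_that("per-center counts are nondecreasing in radius", {
  set.seed(104)
  tb <- random_core(250, width = 300)
  prev <- NULL
  for (r in c(10, 20, 30, 60, 120)) {
    cur <- neighbor_counts(tb, "CD3", c("CD3", "NKp46"), r)$per_center
    if (!is.null(prev)) {
      expect_true(all(cur$CD3 >= prev$CD3))
      expect_true(all(cur$NKp46 >= prev$NKp46))
    }
    prev <- cur
  }
})

test_that("paired in-range counts match construction and the oracle", {
  # center NK at origin with 3 NK and 0 CD3 in range
  tb <- toy_core(x = c(0, 5, -5, 0, 200), y = c(0, 0, 0, 5, 200),
                 NKp46 = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                 CD3 = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  pr <- paired_in_range(tb, "NKp46", "NKp46", "CD3", 30)
  expect_equal(pr$count_a[1], 3)
  expect_equal(pr$count_b[1], 0)
  # degenerate pairing: identical members
  pr2 <- paired_in_range(tb, "NKp46", "CD3", "CD3", 30)
  expect_identical(pr2$count_a, pr2$count_b)
  # random fixture against the brute-force oracle
  set.seed(105)
  rc <- random_core(150, width = 250)
  want <- brute_flag_counts(rc$cells, c("NKp46", "CD3"), 30)
  got <- paired_in_range(rc, "NKp46", "NKp46", "CD3", 30)
  keep <- rc$cells$NKp46
  expect_equal(got$count_a, unname(want[keep, "NKp46"]))
  expect_equal(got$count_b, unname(want[keep, "CD3"]))
})

test_that("flag partition is exact and excludes undefined flags", {
  tb <- toy_core(x = c(0, 10, 20, 30), y = rep(0, 4),
                 CD3 = c(TRUE, TRUE, FALSE, FALSE),
                 MHC1 = c(TRUE, FALSE, NA, TRUE))
  part <- partition_centers_by_flag(tb, "MHC1", "CD3", 30)
  expect_equal(part$pos$n_centers, 2)
  expect_equal(part$neg$n_centers, 1)
  expect_equal(part$n_excluded, 1)
  expect_equal(part$pos$n_centers + part$neg$n_centers + part$n_excluded,
               nrow(tb$cells))
  # all cells positive -> empty negative partition
  tb2 <- toy_core(c(0, 10), c(0, 0), CD3 = c(TRUE, TRUE),
                  MHC1 = c(TRUE, TRUE))
  part2 <- partition_centers_by_flag(tb2, "MHC1", "CD3", 30)
  expect_equal(part2$neg$n_centers, 0)
  expect_true(is.na(part2$neg$summary$mean))
})

test_that("partition means match the brute-force oracle on a fixture", {
  set.seed(106)
  tb <- random_core(300, width = 400)
  tb$cells$MHC1[sample(300, 20)] <- NA
  part <- partition_centers_by_flag(tb, "MHC1", c("CD3", "NKp46"), 30)
  want <- brute_flag_counts(tb$cells, c("CD3", "NKp46"), 30)
  pos <- !is.na(tb$cells$MHC1) & tb$cells$MHC1
  neg <- !is.na(tb$cells$MHC1) & !tb$cells$MHC1
  expect_equal(part$pos$summary$mean, unname(colMeans(want[pos, ])))
  expect_equal(part$neg$summary$mean, unname(colMeans(want[neg, ])))
  expect_equal(part$n_excluded, sum(is.na(tb$cells$MHC1)))
})

test_that("guard margin drops boundary centers and needs geometry", {
  tb <- random_core(50, width = 100)
  expect_error(neighbor_counts(tb, "CD3", "CD3", 30, guard_margin = TRUE),
               "geometry")
  cfg <- point_process_config()
  core <- simulate_core(cfg, seed = 9)
  all_c <- neighbor_counts(core, "CD3", "CD3", 30)
  grd <- neighbor_counts(core, "CD3", "CD3", 30, guard_margin = TRUE)
  expect_lt(grd$n_centers, all_c$n_centers)
  d <- sqrt(core$cells$x^2 + core$cells$y^2)
  expect_equal(grd$n_centers, sum(core$cells$CD3 & d <= 500 - 30))
})

test_that("density/expression correlation recovers exact linear relations", {
  mk <- function(dens_mm2, pid) {
    n <- max(1, round(dens_mm2))   # area 1 mm^2 -> n cells = density
    toy_core(seq_len(n), rep(1, n), CD3 = rep(TRUE, n), area_um2 = 1e6,
             core_id = paste0("c", pid), patient_id = pid)
  }
  dens <- c(10, 20, 30, 40, 50)
  cores <- mapply(mk, dens, sprintf("P%d", 1:5), SIMPLIFY = FALSE)
  expr_lin <- data.frame(patient_id = sprintf("P%d", 1:5),
                         value = 2 * dens + 1)
  expect_equal(density_expression_correlation(cores, "CD3", expr_lin)$r, 1)
  expr_anti <- data.frame(patient_id = sprintf("P%d", 1:5), value = -dens)
  expect_equal(density_expression_correlation(cores, "CD3", expr_anti)$r, -1)
  expect_error(density_expression_correlation(cores[1:2], "CD3",
                                              expr_lin[1:2, ]), ">= 3")
})
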