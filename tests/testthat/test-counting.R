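test_that("bound-peptide counts match static configurations", {
  df <- tidyr::expand_grid(time_ns = 0:9, particle_id = 1:4)
  df$z_nm <- df$particle_id * 1.0 # peptides pinned at 1, 2, 3, 4 nm
  cs <- count_bound_peptides(df, cutoff = 3.5)
  expect_equal(cs$mean, 3)
  expect_equal(cs$sem, 0)

  far <- dplyr::mutate(df, z_nm = z_nm + 10)
  expect_equal(count_bound_peptides(far, cutoff = 3.5)$mean, 0)
  expect_error(count_bound_peptides(df, cutoff = NULL), "required")
})

test_that("bound-peptide counts agree exactly with a brute-force recount", {
  toy <- toy_contact_trajectory(n_peptides = 8, frames = 60, seed = 21)
  cut <- structure(list(z_cut = 3.5, method = "user", rho_min = NA),
                   class = "cutoff_result")
  cs <- count_bound_peptides(toy$peptides, cut)
  # brute force: loop over frames and peptides
  truth_by_frame <- vapply(
    sort(unique(toy$truth$time_ns)),
    function(t) sum(toy$truth$bound[toy$truth$time_ns == t]),
    numeric(1)
  )
  expect_equal(cs$per_frame$value, truth_by_frame)
  expect_equal(cs$mean, mean(truth_by_frame))
})

test_that("buried guanidinium counts reproduce the generator labels exactly", {
  toy <- toy_contact_trajectory(n_peptides = 5, frames = 40, seed = 8)
  cs <- count_buried_gdm(toy$gdm, toy$phosphates, toy$bound_flags)
  truth <- toy$truth[toy$truth$bound, ]
  per_frame_truth <- as.numeric(tapply(truth$buried, truth$time_ns, mean))
  expect_equal(cs$per_frame$value, per_frame_truth)
  expect_equal(cs$mean, mean(per_frame_truth))
  expect_true(cs$mean >= 0 && cs$mean <= 9)
})

test_that("static burial constructions give exact counts", {
  # one bound peptide, 5 of 9 gdm carbons below the phosphate plane
  frames <- 0:4
  gdm <- tidyr::expand_grid(time_ns = frames, slot = 1:9)
  gdm$peptide_id <- 1L
  gdm$z_nm <- ifelse(gdm$slot <= 5, 1.8, 2.6)
  phos <- tidyr::expand_grid(time_ns = frames, k = 1:4)
  phos$z_nm <- 2.0 + c(-0.1, -0.05, 0.05, 0.1)[phos$k]
  flags <- tibble::tibble(time_ns = frames, peptide_id = 1L, bound = TRUE)
  cs <- count_buried_gdm(gdm[c("time_ns", "peptide_id", "z_nm")], phos, flags)
  expect_equal(cs$mean, 5)

  gdm$z_nm <- 2.6 # nothing buried
  cs0 <- count_buried_gdm(gdm[c("time_ns", "peptide_id", "z_nm")], phos, flags)
  expect_equal(cs0$mean, 0)

  flags$bound <- FALSE
  expect_error(
    count_buried_gdm(gdm[c("time_ns", "peptide_id", "z_nm")], phos, flags),
    "undefined"
  )
})

test_that("area per lipid satisfies its defining identity", {
  frames <- tibble::tibble(time_ns = 0:99, lx_nm = 8, ly_nm = 8)
  apl <- area_per_lipid(frames, n_lipids_per_leaflet = 100)
  expect_equal(unique(apl$apl_nm2), 0.64)
  expect_equal(attr(apl, "sem"), 0)

  set.seed(11)
  fl <- tibble::tibble(time_ns = 0:199, lx_nm = 8 + rnorm(200, sd = 0.05),
                       ly_nm = 8 + rnorm(200, sd = 0.05))
  apl2 <- area_per_lipid(fl, 100, discard_ns = 50)
  kept <- fl[fl$time_ns >= 50, ]
  expect_equal(apl2$apl_nm2 * 100, kept$lx_nm * kept$ly_nm) # exact identity
  expect_equal(attr(apl2, "mean"), mean(kept$lx_nm * kept$ly_nm / 100))
  expect_error(area_per_lipid(tibble::tibble(time_ns = 0, lx_nm = 0,
                                             ly_nm = 5), 100), "zero")
})

test_that("minimum periodic distances match direct evaluation and O(N^2) scan", {
  a <- tibble::tibble(time_ns = 0, x_nm = 0, y_nm = 0, z_nm = 0)
  b <- tibble::tibble(time_ns = 0, x_nm = 0, y_nm = 0, z_nm = 2)
  expect_equal(min_distance_series(a, b, c(10, 10, 10))$min_dist_nm, 2)

  # periodic image across the box boundary
  b2 <- tibble::tibble(time_ns = 0, x_nm = 0, y_nm = 0, z_nm = 9)
  a2 <- tibble::tibble(time_ns = 0, x_nm = 0, y_nm = 0, z_nm = 1)
  expect_equal(min_distance_series(a2, b2, c(10, 10, 10))$min_dist_nm, 2)

  set.seed(9)
  mkatoms <- function(n) {
    tibble::tibble(time_ns = rep(0:2, each = n),
                   x_nm = runif(3 * n, 0, 12), y_nm = runif(3 * n, 0, 12),
                   z_nm = runif(3 * n, 0, 12))
  }
  A <- mkatoms(20)
  B <- mkatoms(20)
  res <- min_distance_series(A, B, c(12, 12, 12))
  for (t in 0:2) {
    expect_equal(
      res$min_dist_nm[res$time_ns == t],
      brute_min_distance(
        as.matrix(A[A$time_ns == t, c("x_nm", "y_nm", "z_nm")]),
        as.matrix(B[B$time_ns == t, c("x_nm", "y_nm", "z_nm")]),
        c(12, 12, 12)
      )
    )
  }
})

test_that("block SEM uses the spread of block means", {
  x <- rep(c(1, 2, 3, 4, 5), each = 20)
  expect_equal(pepmem:::block_sem(x, 5), sd(1:5) / sqrt(5))
})
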