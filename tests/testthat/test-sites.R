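blob <- function(center, n, spread = 0.4, seed = 1) {
  withr::with_seed(seed, data.frame(
    x = center[1] + stats::runif(n, -spread, spread),
    y = center[2] + stats::runif(n, -spread, spread),
    z = center[3] + stats::runif(n, -spread, spread),
    energy = -1, lin = seq_len(n)))
}

test_that("single-linkage clustering separates distant blobs", {
  cutoff <- 0.9 * sqrt(3) + 1e-9
  pts <- rbind(blob(c(0, 0, 0), 12, seed = 1),
               blob(c(10 * cutoff, 0, 0), 8, seed = 2))
  pts$lin <- seq_len(nrow(pts))
  cl <- cluster_points(pts, linkage_cutoff = cutoff)
  expect_length(cl, 2)
  expect_equal(vapply(cl, nrow, 0L), c(12L, 8L))  # largest first

  one <- cluster_points(pts[1, ], linkage_cutoff = cutoff)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), 1)
  expect_length(cluster_points(pts[0, ]), 0)
})

test_that("at most max_clusters survive, and clusters partition points", {
  ## 40 singletons pairwise beyond cutoff collapse to the 15 largest
  pts <- data.frame(x = seq(0, by = 5, length.out = 40), y = 0, z = 0,
                    energy = -seq(0.1, 4, length.out = 40),
                    lin = 1:40)
  cl <- cluster_points(pts, max_clusters = 15, linkage_cutoff = 1.6)
  expect_length(cl, 15)
  ## all singletons tie on size; the most favorable energies are kept
  kept_e <- sort(unlist(lapply(cl, `[[`, "energy")))
  expect_equal(kept_e, sort(pts$energy)[1:15])

  withr::local_seed(33)
  pts2 <- data.frame(x = stats::runif(150, 0, 12),
                     y = stats::runif(150, 0, 12),
                     z = stats::runif(150, 0, 12), energy = -1, lin = 1:150)
  cl2 <- cluster_points(pts2, max_clusters = 15, linkage_cutoff = 2.5)
  expect_lte(length(cl2), 15)
  ## no point appears in two clusters
  lins <- unlist(lapply(cl2, `[[`, "lin"))
  expect_equal(anyDuplicated(lins), 0)
  expect_true(all(lins %in% pts2$lin))

  ## clusters agree with an independent single-linkage cut (hclust)
  d <- stats::dist(pts2[, c("x", "y", "z")])
  memb <- stats::cutree(stats::hclust(d, method = "single"), h = 2.5)
  cl_all <- cluster_points(pts2, max_clusters = 1e6, linkage_cutoff = 2.5)
  expect_equal(length(cl_all), length(unique(memb)))
  got_sets <- lapply(cl_all, function(g) sort(g$lin))
  want_sets <- unname(lapply(split(seq_len(150), memb), sort))
  expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                  vapply(want_sets, paste, "", collapse = ","))
})

test_that("site atoms are the union of in-radius atoms", {
  ch <- toy_chain(c(0, 5, 20), chain_id = "A")
  far <- data.frame(x = 100, y = 100, z = 100)
  expect_equal(nrow(site_atoms(far, ch)), 0)

  near <- data.frame(x = 1.5, y = 0, z = 0)
  expect_equal(site_atoms(near, ch, radius = 1.6)$serial, 1L)

  withr::local_seed(23)
  cl <- data.frame(x = stats::runif(30, 0, 20), y = stats::runif(30, 0, 20),
                   z = stats::runif(30, 0, 20))
  ch2 <- random_chain(50)
  got <- site_atoms(cl, ch2, radius = 3)
  want <- unique(unlist(lapply(seq_len(30), function(i) {
    which(sqrt((ch2$x - cl$x[i])^2 + (ch2$y - cl$y[i])^2 +
               (ch2$z - cl$z[i])^2) <= 3)
  })))
  expect_setequal(got$serial, ch2$serial[want])
})

test_that("ranking is monotone in propensity and deterministic on ties", {
  tabs <- toy_tables()
  ch <- toy_chain(c(0, 30), residue_type = c("TRP", "GLY"))
  mk <- function(center, rip, n = 4) {
    data.frame(x = center + seq(0, 0.3, length.out = n), y = 0, z = 0,
               energy = -1, lin = seq_len(n) + round(center * 10),
               rip_score = rip, hydro_score = 0, solv_score = 0,
               overall = rip)
  }
  lo <- mk(0, rip = 0.1)
  hi <- mk(30, rip = 5)
  sites <- rank_sites(list(lo, hi), ch, tabs, site_radius = 1.6)
  expect_equal(sites[[1]]$points$rip_score[1], 5)   # higher propensity wins
  expect_equal(sites[[1]]$rank, 1)

  ## identical clusters tie and keep a stable, lin-ordered ranking
  dup <- rank_sites(list(lo, lo), ch, tabs, site_radius = 1.6)
  expect_equal(vapply(dup, `[[`, 0L, "rank"), 1:2)
  expect_equal(dup[[1]]$points, dup[[2]]$points)

  ## engineered winner: same propensity, far deeper energy
  deep <- mk(30, rip = 0.1); deep$energy <- -50
  s2 <- rank_sites(list(lo, deep), ch, tabs, site_radius = 1.6)
  expect_equal(s2[[1]]$total_energy, sum(deep$energy))
})

test_that("overlap score is the harmonic precision/coverage mean", {
  A <- toy_chain(1:10, residue_seq = 1:10)
  expect_equal(site_overlap_score(A, A), 1)
  expect_equal(site_overlap_score(toy_chain(101:110, residue_seq = 101:110), A), 0)
  ## |P ∩ A| = 5 with |P| = |A| = 10 gives tau = 0.5
  P <- toy_chain(6:15, residue_seq = 6:15)
  expect_equal(site_overlap_score(P, A), 0.5)
  detail <- site_overlap_score(P, A, detail = TRUE)
  expect_equal(detail$precision, 0.5)
  expect_equal(detail$coverage, 0.5)

  expect_equal(site_overlap_score(A[0, ], A), 0)
  expect_error(site_overlap_score(A, A[0, ]), "empty")

  ## invariant to atom ordering and to the roles within the formula
  withr::local_seed(31)
  perm <- A[sample(10), ]
  expect_equal(site_overlap_score(P, perm), site_overlap_score(P, A))

  ## on asymmetric overlaps the combiners order as
  ## min(p, c) <= harmonic mean <= max(p, c)
  P2 <- toy_chain(8:20, residue_seq = 8:20)  # p = 3/13, c = 3/10
  h <- site_overlap_score(P2, A)
  m <- site_overlap_score(P2, A, method = "min")
  d <- site_overlap_score(P2, A, detail = TRUE)
  expect_lte(m, h + 1e-12)
  expect_lte(h, max(d$precision, d$coverage) + 1e-12)

  ## nested predictions have monotone coverage
  covs <- vapply(list(toy_chain(1:2, residue_seq = 1:2),
                      toy_chain(1:5, residue_seq = 1:5),
                      toy_chain(1:9, residue_seq = 1:9)),
                 function(p) site_overlap_score(p, A, detail = TRUE)$coverage,
                 0)
  expect_true(all(diff(covs) >= 0))
})

test_that("top-k evaluation applies the inclusive 0.25 threshold", {
  mk_site <- function(serials, rank) {
    structure(list(rank = rank, points = data.frame(),
                   atoms = toy_chain(serials, residue_seq = serials),
                   tau = NA_real_),
              class = "predicted_site")
  }
  actual <- toy_chain(1:16, residue_seq = 1:16)
  ## |P ∩ A| / harmonic construction giving tau exactly 0.25:
  ## p = 4/16, c = 4/16 -> tau = 0.25
  boundary <- mk_site(c(1:4, 101:112), 1)
  ev <- evaluate_topk(list(boundary), actual, k = 1)
  expect_equal(ev$best_tau, 0.25)
  expect_true(ev$correct)

  below <- mk_site(c(1:3, 101:113), 1)  # p = c = 3/16 -> tau < 0.25
  ev2 <- evaluate_topk(list(below), actual, k = 1)
  expect_lt(ev2$best_tau, 0.25)
  expect_false(ev2$correct)

  ## k = 2 best tau is never worse than k = 1
  good <- mk_site(1:16, 2)
  ev_k1 <- evaluate_topk(list(below, good), actual, k = 1)
  ev_k2 <- evaluate_topk(list(below, good), actual, k = 2)
  expect_gte(ev_k2$best_tau, ev_k1$best_tau)
  expect_equal(ev_k2$best_tau, 1)

  ## no predictions at all
  ev0 <- evaluate_topk(list(), actual, k = 1)
  expect_false(ev0$correct)
  expect_equal(ev0$best_tau, 0)
})
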