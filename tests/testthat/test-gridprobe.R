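test_that("grid box covers the chain plus padding at the stated spacing", {
  ch <- toy_chain(0)
  g <- build_grid(ch, spacing = 0.9, padding = 4.5)
  expect_equal(g$dims, rep(11L, 3))      # -4.5 ... +4.5 in 0.9 steps
  expect_equal(g$origin, rep(-4.5, 3))

  withr::local_seed(4)
  ch2 <- random_chain(25)
  g1 <- build_grid(ch2, spacing = 0.9)
  g2 <- build_grid(ch2, spacing = 1.8)
  expect_lt(prod(g2$dims), prod(g1$dims) / 6)  # roughly an eighth
  ## every atom lies inside the box
  top <- g1$origin + (g1$dims - 1) * g1$spacing
  expect_true(all(ch2$x >= g1$origin[1] & ch2$x <= top[1]))
  expect_true(all(ch2$y >= g1$origin[2] & ch2$y <= top[2]))
  expect_true(all(ch2$z >= g1$origin[3] & ch2$z <= top[3]))
})

test_that("probe energy has the 12-6 form with cutoff and clamp", {
  params <- load_probe_params()
  ch <- toy_chain(0)  # one carbon at origin
  eps_ij <- sqrt(0.150 * params$probe$epsilon)
  rmin_ij <- 2.00 + params$probe$rmin

  ## exactly -eps at the pair minimum distance
  expect_equal(probe_energy(c(rmin_ij, 0, 0), ch, params), -eps_ij,
               tolerance = 1e-9)
  ## zero beyond the cutoff
  expect_equal(probe_energy(c(9, 0, 0), ch, params), 0)
  expect_lt(abs(probe_energy(c(8.01, 0, 0), ch, params)), 1e-6)
  ## clamped at the core
  expect_equal(probe_energy(c(0, 0, 0), ch, params), 1e3)
})

test_that("grid energies equal the unoptimized per-point double loop", {
  withr::local_seed(8)
  ch <- random_chain(10, span = 6)
  params <- load_probe_params()
  g <- build_grid(ch, spacing = 2.0, padding = 4.0)
  E <- grid_energies(g, ch, params)

  ## independent oracle: explicit loop over points and atoms
  pair <- function(el) list(eps = sqrt(params$elements$epsilon[
    match(el, params$elements$element)] * params$probe$epsilon),
    rmin = params$elements$rmin[match(el, params$elements$element)] +
      params$probe$rmin)
  oracle <- array(0, dim = g$dims)
  for (i in seq_len(g$dims[1])) for (j in seq_len(g$dims[2])) {
    for (k in seq_len(g$dims[3])) {
      p <- g$origin + (c(i, j, k) - 1) * g$spacing
      e <- 0
      for (a in seq_len(nrow(ch))) {
        pr <- pair(ch$element[a])
        r2 <- max(sum((c(ch$x[a], ch$y[a], ch$z[a]) - p)^2), 1e-4)
        if (r2 > 64) next
        t <- (pr$rmin^2 / r2)^3
        e <- e + pr$eps * (t * t - 2 * t)
      }
      oracle[i, j, k] <- min(e, 1e3)
    }
  }
  expect_equal(E, oracle, tolerance = 1e-9)

  ## and the single-point entry agrees
  p0 <- g$origin + 3 * g$spacing
  expect_equal(probe_energy(p0, ch, params), oracle[4, 4, 4],
               tolerance = 1e-9)
})

test_that("energies are invariant under rigid translation", {
  withr::local_seed(12)
  ch <- random_chain(15, span = 8)
  g <- build_grid(ch, spacing = 1.5)
  E <- grid_energies(g, ch)
  shift <- c(13.7, -4.2, 8.9)
  ch2 <- ch; ch2$x <- ch$x + shift[1]; ch2$y <- ch$y + shift[2]
  ch2$z <- ch$z + shift[3]
  g2 <- g; g2$origin <- g$origin + shift
  expect_equal(grid_energies(g2, ch2), E, tolerance = 1e-9)
})

test_that("favorable-point retention filters the energy field exactly", {
  withr::local_seed(14)
  ch <- random_chain(20, span = 10)
  g <- build_grid(ch, spacing = 1.2)
  E <- grid_energies(g, ch)
  pts <- retain_favorable(g, threshold = -1.0, energies = E)
  expect_equal(nrow(pts), sum(E < -1.0))
  expect_true(all(pts$energy < -1.0))
  expect_equal(pts$energy, E[cbind(pts$ix, pts$iy, pts$iz)])
  ## coords reconstruct from origin + index * spacing
  expect_equal(pts$x, g$origin[1] + (pts$ix - 1) * g$spacing)
  ## monotone in the threshold
  n_each <- vapply(c(-0.5, -1, -1.5, -2), function(th) {
    nrow(retain_favorable(g, threshold = th, energies = E))
  }, 0L)
  expect_true(all(diff(n_each) <= 0))
  expect_error(retain_favorable(g, threshold = 0.5, energies = E))
})

test_that("grid-point propensity sums per-atom scores within the radius", {
  gly2 <- propensity_table("toy", stats::setNames(
    c(2.0, rep(1, 19)),
    c("GLY", setdiff(names(default_atom_counts()), "GLY"))))

  ch <- toy_chain(c(0, 10), residue_type = "GLY")
  expect_equal(grid_point_propensity(c(5, 0, 0), ch, gly2), 0)
  expect_equal(grid_point_propensity(c(1.5, 0, 0), ch, gly2, radius = 1.6),
               2.0)

  ## random toys against a brute-force neighbor scan
  withr::local_seed(17)
  ch2 <- random_chain(40, span = 10)
  ch2$residue_type <- sample(names(default_atom_counts()), 40, replace = TRUE)
  hydro <- hydrophobicity_table()
  pts <- data.frame(x = stats::runif(25, 0, 10), y = stats::runif(25, 0, 10),
                    z = stats::runif(25, 0, 10))
  for (r in c(1.6, 5.0)) {
    got <- points_propensity(pts, ch2, hydro, radius = r)
    want <- vapply(seq_len(25), function(i) {
      s <- 0
      for (a in seq_len(40)) {
        d <- sqrt((ch2$x[a] - pts$x[i])^2 + (ch2$y[a] - pts$y[i])^2 +
                  (ch2$z[a] - pts$z[i])^2)
        if (d <= r) s <- s + per_atom_score(ch2$residue_type[a], hydro)
      }
      s
    }, 0)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(grid_point_propensity(unlist(pts[3, ]), ch2, hydro, r),
                 want[3], tolerance = 1e-12)
  }
})

test_that("overall propensity is a weighted standardized combination", {
  pts <- data.frame(rip_score = c(0, 0, 0), hydro_score = c(0, 0, 0),
                    solv_score = c(0, 0, 0))
  expect_equal(overall_propensity(pts), c(0, 0, 0))

  withr::local_seed(19)
  pts2 <- data.frame(rip_score = stats::rnorm(10),
                     hydro_score = stats::rnorm(10),
                     solv_score = stats::rnorm(10))
  ## projection weights without standardization return the raw column
  expect_equal(overall_propensity(pts2, c(1, 0, 0), standardize = FALSE),
               pts2$rip_score)
  ## default equals the hand-built z-score sum
  z <- function(v) (v - mean(v)) / stats::sd(v)
  expect_equal(overall_propensity(pts2),
               z(pts2$rip_score) + z(pts2$hydro_score) + z(pts2$solv_score),
               tolerance = 1e-12)
})
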