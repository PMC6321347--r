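test_that("bond criterion uses 20% over the covalent-radius sum", {
  # r_ref(H,H) = 1.2 * (0.31 + 0.31) = 0.744
  h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  cg <- build_connectivity(h2)
  expect_equal(cg$r_ref[1, 2], 0.744)
  expect_equal(cg$A[1, 2], 1)

  far <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(build_connectivity(far)$A[1, 2], 0)

  single <- geometry("C", matrix(0, 1, 3))
  expect_equal(build_connectivity(single)$A, matrix(0, 1, 1))

  expect_error(geometry("Xx", matrix(0, 1, 3)), "Xx")
})

test_that("weighted adjacency follows the (6,12) closed form", {
  expect_equal(weighted_adjacency_value(1), 0.5)          # removable point
  expect_equal(weighted_adjacency_value(2), 1 / 65)
  expect_equal(weighted_adjacency_value(1e-9), 1, tolerance = 1e-12)
  # strictly decreasing in distance
  x <- seq(0.1, 3, length.out = 300)
  expect_true(all(diff(weighted_adjacency_value(x)) < 0))
  # generic exponents fill the singularity with the n/m limit
  expect_equal(weighted_adjacency_value(1, n_exp = 4, m_exp = 6), 4 / 6)
  # coincident atoms are rejected
  dup <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(build_weighted(dup), "coincident")
})

test_that("labeled adjacency carries 1 + Z/10 on the diagonal", {
  ch2o <- read_xyz(test_path_extdata("ch2o.xyz"))
  lg <- build_labeled(build_connectivity(ch2o))
  expect_equal(diag(lg$AZ), c(1.6, 1.8, 1.1, 1.1))  # C, O, H, H
  # like-atom swap leaves the sorted spectrum unchanged
  perm <- c(1, 2, 4, 3)
  swapped <- geometry(ch2o$symbols[perm], ch2o$coords[perm, ])
  expect_equal(labeled_spectrum(build_labeled(build_connectivity(swapped))),
               labeled_spectrum(lg), tolerance = 1e-10)
})

test_that("Laplacian spectra give fragment counts and the spectral gap", {
  h2 <- build_connectivity(
    geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.7, 0, 0))))
  sp <- laplacian_spectrum(h2)
  expect_equal(sp$eigenvalues, c(0, 2), tolerance = 1e-12)
  expect_equal(sp$n_fragments, 1)
  expect_equal(sp$spectral_gap, 2)

  apart <- build_connectivity(
    geometry(c("H", "H"), rbind(c(0, 0, 0), c(9, 0, 0))))
  sp2 <- laplacian_spectrum(apart)
  expect_equal(sp2$eigenvalues, c(0, 0))
  expect_equal(sp2$n_fragments, 2)

  # bonded triangle: known K3 spectrum {0, 3, 3}
  tri <- build_connectivity(
    geometry(c("C", "C", "C"), 1.4 * rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0.5, sqrt(3) / 2, 0))))
  expect_equal(laplacian_spectrum(tri)$eigenvalues, c(0, 3, 3),
               tolerance = 1e-12)

  expect_error(laplacian_spectrum(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("fragment counting matches worked geometries and the traversal labels", {
  h2o <- read_xyz(test_path_extdata("h2o.xyz"))
  expect_equal(count_fragments(h2o)$n_fragments, 1)

  detached <- h2o
  detached$coords[2, 1] <- detached$coords[2, 1] + 10
  fr <- count_fragments(detached)
  expect_equal(fr$n_fragments, 2)
  expect_equal(fr$labels, c(1, 2, 1))

  iso <- geometry(rep("O", 5), cbind(6 * (0:4), 0, 0))
  expect_equal(count_fragments(iso)$n_fragments, 5)
})

test_that("Laplacian fragment count agrees with an igraph traversal oracle", {
  skip_if_not_installed("igraph")
  set.seed(401)
  for (k in 1:150) {
    g <- random_geometry()
    A <- build_connectivity(g)$A
    expect_equal(count_fragments(g)$n_fragments, igraph_components(A))
  }
})

test_that("unweighted Laplacians are positive semidefinite with a zero mode", {
  set.seed(402)
  for (k in 1:50) {
    A <- random_adjacency()
    sp <- laplacian_spectrum(A)
    expect_gte(sp$eigenvalues[1], -1e-9)
    expect_lt(abs(sp$eigenvalues[1]), 1e-9)
  }
})

test_that("SPRINT coordinates are invariant and match the diatomic value", {
  # homonuclear diatomic at r = r_ref: weights 0.5, lambda = 0.5, s_i = 0.5
  h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.744, 0, 0)))
  s <- sprint_coordinates(build_weighted(h2))
  expect_equal(s$sprint, c(0.5, 0.5), tolerance = 1e-12)

  set.seed(403)
  g <- random_geometry(8)
  ref <- sprint_coordinates(build_weighted(g))
  # atom permutation
  p <- sample(8)
  gp <- geometry(g$symbols[p], g$coords[p, ])
  expect_equal(sprint_coordinates(build_weighted(gp))$sprint, ref$sprint,
               tolerance = 1e-10)
  # rigid rotation + translation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  gr <- geometry(g$symbols, g$coords %*% R + matrix(2.5, 8, 3))
  expect_equal(sprint_coordinates(build_weighted(gr))$sprint, ref$sprint,
               tolerance = 1e-10)
})

test_that("stretching a bond monotonically closes the weighted spectral gap", {
  gaps <- vapply(seq(1.5, 2.4, length.out = 10), function(f) {
    g <- geometry(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5 + 1.5 * f, 0, 0)))
    laplacian_spectrum(build_weighted(g))$spectral_gap
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})
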