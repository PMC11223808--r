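# Network geometry, Tirion energy/gradient/Hessian, spring-constant scaling.

test_that("cutoff network matches the brute-force distance scan", {
  # collinear triad
  pts <- cbind(c(0, 5, 10), 0, 0)
  n1 <- build_cutoff_network(pts, cutoff = 6, k = 1)
  expect_equal(cbind(n1$i, n1$j), cbind(c(1, 2), c(2, 3)))
  n2 <- build_cutoff_network(pts, cutoff = 12, k = 1)
  expect_equal(length(n2$i), 3)
  # 50 random points vs O(N^2) oracle
  xyz <- random_cloud(50, box = 25, seed = 21)
  net <- suppressWarnings(build_cutoff_network(xyz, cutoff = 8, k = 1))
  d <- as.matrix(dist(xyz))
  want <- which(upper.tri(d) & d <= 8, arr.ind = TRUE)
  expect_setequal(edge_key(cbind(net$i, net$j)), edge_key(want))
  # rest lengths equal reference distances
  expect_equal(net$r0, d[cbind(net$i, net$j)], tolerance = 1e-12)
})

test_that("isolated atoms are a hard error", {
  pts <- rbind(cbind(c(0, 3, 6), 0, 0), c(100, 0, 0))
  expect_error(build_cutoff_network(pts, cutoff = 8, k = 1), "isolated")
})

test_that("Delaunay network reproduces closed-form and brute-force cases", {
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8.66, 0), c(5, 2.89, 8.16))
  # 4 vertices of a tetrahedron: all 6 edges
  jit <- matrix(c(0.01, -0.02, 0.013, 0.007, -0.011, 0.003,
                  -0.006, 0.009, -0.014, 0.012, 0.004, -0.008), 4, 3)
  five <- rbind(tet + jit, colMeans(tet))
  net5 <- build_delaunay_network(five, k = 1)
  keys <- edge_key(cbind(net5$i, net5$j))
  # centre connected to all four vertices
  expect_true(all(paste(1:4, 5) %in% keys))
  # brute-force empty-circumsphere oracle agrees exactly
  expect_setequal(keys, edge_key(brute_delaunay_edges(five)))
})

test_that("Delaunay edges on random clouds satisfy the brute-force oracle and sanity bounds", {
  for (sd in c(31, 32)) {
    xyz <- random_cloud(10, box = 12, seed = sd)
    net <- build_delaunay_network(xyz, k = 1)
    expect_setequal(edge_key(cbind(net$i, net$j)),
                    edge_key(brute_delaunay_edges(xyz)))
  }
  big <- random_cloud(100, box = 30, seed = 33)
  netb <- build_delaunay_network(big, k = 1)
  expect_lt(length(netb$i), 8 * 100)
  comps <- igraph::components(igraph::graph_from_edgelist(
    cbind(netb$i, netb$j), directed = FALSE))
  expect_equal(comps$no, 1)
})

test_that("Tirion energy is the half-k sum of squared length deviations", {
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  net <- build_cutoff_network(two, cutoff = 4, k = 2)
  expect_equal(tirion_energy(net, two), 0)
  stretched <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(tirion_energy(net, stretched), 0.5 * 2 * (5 - 3)^2)
  # term-by-term oracle on a 20-atom net
  tn <- toy_net(20, seed = 22, k = 0.7)
  set.seed(23)
  x <- vec3(tn$xyz) + rnorm(60, sd = 0.5)
  xm <- matrix(x, ncol = 3, byrow = TRUE)
  manual <- 0
  for (e in seq_along(tn$net$i)) {
    r <- sqrt(sum((xm[tn$net$i[e], ] - xm[tn$net$j[e], ])^2))
    manual <- manual + 0.5 * 0.7 * (r - tn$net$r0[e])^2
  }
  expect_equal(tirion_energy(tn$net, x), manual, tolerance = 1e-12)
})

test_that("gradient is analytic: zero at rest, 1-D spring form, FD agreement", {
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  net <- build_cutoff_network(two, cutoff = 4, k = 2)
  expect_equal(tirion_gradient(net, two), rep(0, 6))
  g <- tirion_gradient(net, rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(g, c(-2 * (5 - 3), 0, 0, 2 * (5 - 3), 0, 0))
  tn <- toy_net(12, seed = 24)
  set.seed(25)
  x <- vec3(tn$xyz) + rnorm(36, sd = 0.3)
  gfd <- fd_gradient(function(v) tirion_energy(tn$net, v), x)
  expect_equal(tirion_gradient(tn$net, x), gfd, tolerance = 1e-6)
})

test_that("Hessian has the exact block form, rigid kernel, PSD spectrum and FD agreement", {
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  H2 <- assemble_hessian(build_cutoff_network(two, cutoff = 4, k = 1))
  want <- matrix(0, 6, 6)
  want[1, 1] <- want[4, 4] <- 1; want[1, 4] <- want[4, 1] <- -1
  expect_equal(H2$dense, want, tolerance = 1e-14)
  tn <- toy_net(10, seed = 26)
  Hd <- tn$H$dense
  # symmetry under the operator contract
  set.seed(27)
  u <- rnorm(30); v <- rnorm(30)
  expect_equal(sum(u * tn$H$matvec(v)), sum(v * tn$H$matvec(u)),
               tolerance = 1e-10)
  ev <- eigen(Hd, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  # exact rigid-body kernel
  modes <- rigid_body_modes(tn$xyz)
  expect_lt(max(abs(Hd %*% modes)), 1e-8 * max(abs(Hd)))
  # finite-difference Hessian of the Tirion energy at the reference
  Hfd <- fd_hessian_from_grad(function(v) tirion_gradient(tn$net, v),
                              vec3(tn$xyz))
  expect_equal(Hd, Hfd, tolerance = 1e-5)
})

test_that("energy is invariant and gradient covariant under rigid motion", {
  tn <- toy_net(15, seed = 28)
  set.seed(29)
  x <- vec3(tn$xyz) + rnorm(45, sd = 0.4)
  R <- actionpath:::rotation_about_axis(c(1, -1, 2), 1.1)
  tl <- c(3, -2, 7)
  xm <- matrix(x, ncol = 3, byrow = TRUE)
  xr <- sweep(xm %*% t(R), 2, tl, "+")
  expect_equal(tirion_energy(tn$net, xr), tirion_energy(tn$net, x),
               tolerance = 1e-10)
  g <- matrix(tirion_gradient(tn$net, x), ncol = 3, byrow = TRUE)
  gr <- matrix(tirion_gradient(tn$net, vec3(xr)), ncol = 3, byrow = TRUE)
  expect_equal(gr, g %*% t(R), tolerance = 1e-8)
})

test_that("spring constant follows k = A / <B> with range warning", {
  expect_equal(spring_constant_from_bfactor(4, 25), 0.16)
  expect_no_warning(spring_constant_from_bfactor(4, 40))
  expect_warning(k <- spring_constant_from_bfactor(4, 8), "range")
  expect_equal(k, 0.5)
  expect_error(spring_constant_from_bfactor(4, 0), "positive")
})
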