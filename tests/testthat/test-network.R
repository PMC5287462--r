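# Network container, drive scaling, vectorization, FLN/SLN, fixtures.

test_that("network_model validates its inputs", {
  expect_error(network_model(K = matrix(1, 2, 3), J = matrix(1, 2, 3),
                             K_ext = 1, J_ext = 1, nu_ext = 1), "square")
  expect_error(network_model(K = matrix(-1, 1, 1), J = matrix(1, 1, 1),
                             K_ext = 1, J_ext = 1, nu_ext = 1),
               "non-negative")
  expect_error(network_model(K = matrix(1, 1, 1), J = matrix(1, 2, 2),
                             K_ext = 1, J_ext = 1, nu_ext = 1), "shape")
  expect_error(network_model(K = matrix(1, 1, 1), J = matrix(1, 1, 1),
                             K_ext = -1, J_ext = 1, nu_ext = 1), "K_ext")
})

test_that("effective weight matrices are Hadamard products", {
  net <- network_model(K = matrix(3, 2, 2), J = matrix(0.5, 2, 2),
                       K_ext = 1, J_ext = 0.5, nu_ext = 1,
                       weight_unit = "mV")
  ew <- effective_weight_matrices(net)
  expect_equal(ew$W, matrix(1.5, 2, 2), ignore_attr = TRUE)
  expect_equal(ew$W2, matrix(0.75, 2, 2), ignore_attr = TRUE)
  # W2 = W * w elementwise, and W carries J's sign pattern
  net2 <- build_ei_pair()
  ew2 <- effective_weight_matrices(net2)
  expect_equal(ew2$W2, ew2$W * ew2$w_mV, ignore_attr = TRUE)
  expect_equal(sign(ew2$W), sign(net2$J), ignore_attr = TRUE)
})

test_that("drive scaling at kappa = 1 is the exact identity", {
  net <- build_layered_toy()
  out <- apply_drive_scaling(net, drive_scaling(1))
  expect_identical(out, net)
})

test_that("the secondary 6E rule passes through the stated calibration", {
  net <- build_layered_toy()
  i5 <- which(net$labels$layer == "5E")
  i6 <- which(net$labels$layer == "6E")
  out <- apply_drive_scaling(net, drive_scaling(1.15))
  expect_equal(out$K_ext[i5] / net$K_ext[i5], rep(1.15, length(i5)))
  expect_equal(out$K_ext[i6] / net$K_ext[i6], rep(1.5, length(i6)))
  # affine interpolation between the (1, 1) and (1.15, 1.5) endpoints
  out2 <- apply_drive_scaling(net, drive_scaling(1.075))
  expect_equal(out2$K_ext[i6] / net$K_ext[i6], rep(1.25, length(i6)))
  # untouched populations keep their external indegree
  rest <- setdiff(seq_len(net$N), c(i5, i6))
  expect_equal(out$K_ext[rest], net$K_ext[rest])
})

test_that("an empty drive selector warns and returns the network as is", {
  net <- build_single_pop(layer = "23E")
  expect_warning(out <- apply_drive_scaling(net, drive_scaling(1.2)),
                 "no population")
  expect_equal(out$K_ext, net$K_ext)
})

test_that("vectorization is row-major with an exact round trip", {
  expect_equal(vectorize(matrix(1:4, 2, 2, byrow = TRUE)), c(1, 2, 3, 4))
  set.seed(7)
  for (N in 2:5) {
    M <- matrix(rnorm(N * N), N, N)
    expect_equal(devectorize(vectorize(M)), M)
    v <- vectorize(M)
    for (i in seq_len(N)) for (j in seq_len(N))
      expect_identical(v[(i - 1) * N + j], M[i, j])
  }
  expect_error(devectorize(1:5), "square")
})

test_that("FLN rows normalize over external source areas", {
  # two areas, A receives only from B
  K <- rbind(c(0, 5), c(0, 0))
  net <- network_model(K = K, J = matrix(87.8, 2, 2), K_ext = 10,
                       J_ext = 87.8, nu_ext = 10)
  part <- area_partition(c("A", "B"))
  f <- fln(net, part)
  expect_equal(f["A", "B"], 1)
  expect_true("B" %in% attr(f, "undefined_rows"))
  # three areas with 30 and 10 cross-area indegrees into A
  K3 <- matrix(0, 3, 3)
  K3[1, 2] <- 30
  K3[1, 3] <- 10
  K3[2, 1] <- K3[3, 1] <- 5
  net3 <- network_model(K = K3, J = matrix(87.8, 3, 3), K_ext = 10,
                        J_ext = 87.8, nu_ext = 10)
  f3 <- fln(net3, area_partition(c("A", "B", "C")))
  expect_equal(f3["A", "B"], 0.75)
  expect_equal(f3["A", "C"], 0.25)
})

test_that("FLN rows sum to one on a random layered fixture", {
  net <- build_layered_toy(areas = c("X", "Y", "Z"), seed = 3)
  f <- fln(net, attr(net, "partition"))
  sums <- rowSums(f, na.rm = TRUE)
  expect_equal(unname(sums), rep(1, 3), tolerance = 1e-12)
  expect_true(isTRUE(attr(f, "size_weighted")))
})

test_that("SLN is the supragranular share of excitatory projections", {
  net <- build_layered_toy()
  part <- attr(net, "partition")
  s <- sln(net, part)
  offdiag <- s[row(s) != col(s)]
  expect_true(all(offdiag >= 0 & offdiag <= 1, na.rm = TRUE))
  # all cross-area synapses from 2/3E only -> SLN = 1
  K <- net$K
  cross <- outer(part$areas, part$areas, `!=`)
  src_not_sg <- matrix(!part$supragranular, net$N, net$N, byrow = TRUE)
  K[cross & src_not_sg] <- 0
  net1 <- network_model(K = K, J = net$J, K_ext = net$K_ext,
                        J_ext = net$J_ext, nu_ext = net$nu_ext,
                        labels = net$labels, pop_sizes = net$pop_sizes)
  s1 <- sln(net1, part)
  expect_equal(unname(s1[row(s1) != col(s1)]), rep(1, 2))
  # equal synapse counts from 2/3E and 5E -> SLN = 1/2
  K2 <- matrix(0, 4, 4)
  K2[1, 3] <- K2[1, 4] <- 7   # area A receives equally from B's 23E and 5E
  labels <- data.frame(pop = c("A.23E", "A.5E", "B.23E", "B.5E"),
                       area = c("A", "A", "B", "B"),
                       layer = c("23E", "5E", "23E", "5E"),
                       ei = "E")
  net2 <- network_model(K = K2, J = matrix(87.8, 4, 4), K_ext = 10,
                        J_ext = 87.8, nu_ext = 10, labels = labels,
                        pop_sizes = c(100, 100, 100, 100))
  s2 <- sln(net2, area_partition(labels$area,
                                 supragranular = labels$layer == "23E"))
  expect_equal(s2["A", "B"], 0.5)
  expect_error(sln(build_single_pop(), area_partition("A")), "pop_sizes")
})

test_that("fixtures are deterministic and architecture-consistent", {
  a <- build_random_multipop(10, seed = 1)
  b <- build_random_multipop(10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, build_random_multipop(10, seed = 2)))
  # generator does not disturb the caller's RNG stream
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(build_random_multipop(4, seed = 5))
  expect_identical(runif(1), x1)
  # splitting the population in two preserves the total recurrent input
  one <- build_single_pop()
  two <- build_two_pop()
  nu <- 17
  m1 <- input_moments(nu, one)
  m2 <- input_moments(rep(nu, 2), two)
  expect_equal(m2$mu, rep(m1$mu, 2))
  expect_equal(m2$sigma2, rep(m1$sigma2, 2))
})
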