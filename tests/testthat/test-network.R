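# Functional-network construction and the printed-formula graph metrics.

chain3 <- function() net_from_adjacency(
  matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 3, 3))

test_that("adjacency links identical traces and not anti-correlated ones", {
  t0 <- sin(2 * pi * (1:100) / 25)
  tr <- rbind(t0, t0, -t0)
  net <- build_adjacency(tr, R_th = 0.95)
  expect_equal(net$R[1, 2], 1)
  expect_true(net$A[1, 2])
  expect_equal(net$R[1, 3], -1)
  expect_false(net$A[1, 3])
  expect_equal(unname(diag(net$R)), rep(0, 3))
  expect_false(any(diag(net$A)))
})

test_that("constant traces are excluded with a warning", {
  tr <- rbind(sin(1:50), cos(1:50), rep(1, 50), sin(2 * (1:50)))
  expect_warning(net <- build_adjacency(tr), "constant")
  expect_equal(net$n_cells, 3L)
})

test_that("independent Gaussian traces produce no links at R_th 0.95", {
  set.seed(22)
  links <- replicate(20, {
    tr <- matrix(rnorm(20 * 200), 20, 200)
    sum(build_adjacency(tr, R_th = 0.95)$A) / 2
  })
  expect_true(all(links == 0))
})

test_that("percent-links distributions match closed forms", {
  K5 <- net_from_adjacency(matrix(TRUE, 5, 5))
  dd <- degree_distribution(K5)
  expect_equal(unname(dd$percent_links), rep(100, 5))

  star <- matrix(FALSE, 5, 5); star[1, 2:5] <- star[2:5, 1] <- TRUE
  ds <- degree_distribution(net_from_adjacency(star))
  expect_equal(unname(ds$percent_links), c(100, rep(25, 4)))
  expect_equal(ds$n_zero_degree, 0L)
})

test_that("mean percent links tracks the edge probability of random graphs", {
  set.seed(23)
  m <- replicate(50, {
    A <- random_adjacency(30, 0.2)
    degree_distribution(net_from_adjacency(A))$mean_percent
  })
  expect_equal(mean(m), 20, tolerance = 3 / 20)
})

test_that("average pairwise correlation matches hand enumeration and a naive loop", {
  t0 <- sin(2 * pi * (1:80) / 16)
  same <- rbind(t0, t0, t0)
  rp <- mean_pairwise_correlation(build_adjacency(same))
  expect_equal(rp$R_avg, 1)
  expect_equal(rp$R_sd, 0)

  # two anti-correlated halves of two cells each: (2*1 + 4*(-1)) / 6
  anti <- rbind(t0, t0, -t0, -t0)
  expect_equal(mean_pairwise_correlation(build_adjacency(anti))$R_avg, -1 / 3)

  set.seed(24)
  tr <- matrix(rnorm(8 * 60), 8, 60)
  net <- build_adjacency(tr)
  acc <- c()
  for (i in 1:7) for (j in (i + 1):8) acc <- c(acc, cor(tr[i, ], tr[j, ]))
  expect_equal(mean_pairwise_correlation(net)$R_avg, mean(acc))
  expect_equal(mean_pairwise_correlation(net)$R_sd, sd(acc))
})

test_that("hub classification uses the >= 25% boundary convention", {
  # n = 9, a cell with 2 links sits exactly at 2/8 = 25%
  A <- matrix(FALSE, 9, 9)
  A[1, 2:3] <- A[2:3, 1] <- TRUE
  net <- net_from_adjacency(A)
  expect_equal(hub_fraction(net), 1 / 9)         # only the center qualifies
  expect_equal(hub_fraction(net, strict = TRUE), 0)

  star <- matrix(FALSE, 5, 5); star[1, 2:5] <- star[2:5, 1] <- TRUE
  expect_equal(hub_fraction(net_from_adjacency(star)), 1)
  expect_equal(hub_fraction(net_from_adjacency(matrix(FALSE, 5, 5))), 0)
})

test_that("the clustering coefficient is normalized degree, as printed", {
  A <- matrix(FALSE, 4, 4)
  A[1, 2:3] <- A[2:3, 1] <- TRUE
  cc <- clustering_coefficient(net_from_adjacency(A))
  expect_equal(cc$C[1], 2 / 3)
  expect_equal(clustering_coefficient(net_from_adjacency(matrix(TRUE, 6, 6)))$C_avg, 1)

  set.seed(25)
  for (i in 1:5) {
    A <- random_adjacency(10, 0.3)
    net <- net_from_adjacency(A)
    expect_equal(clustering_coefficient(net)$C_avg,
                 mean(colSums(A) / 9))
  }
})

test_that("shortest paths agree with a Floyd-Warshall oracle on random graphs", {
  set.seed(26)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.5))
    D1 <- shortest_paths_matrix(net_from_adjacency(A))
    D2 <- floyd_warshall(A)
    expect_equal(unname(D1), unname(D2))
  }
})

test_that("path length and efficiency match hand-enumerated closed forms", {
  ch <- chain3()
  paths <- shortest_paths_matrix(ch)
  expect_equal(paths[1, 3], 2)
  expect_equal(characteristic_path_length(paths), 4 / 3)
  expect_equal(global_efficiency(paths), 5 / 6)

  K3 <- net_from_adjacency(matrix(TRUE, 3, 3))
  pk <- shortest_paths_matrix(K3)
  expect_equal(characteristic_path_length(pk), 1)
  expect_equal(global_efficiency(pk), 1)

  # two disjoint edges on 4 nodes: unreachable pairs contribute nothing
  A <- matrix(FALSE, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- TRUE
  pd <- shortest_paths_matrix(net_from_adjacency(A))
  expect_true(is.infinite(pd[1, 3]))
  expect_equal(characteristic_path_length(pd), 1 / 3)
  expect_equal(global_efficiency(pd), 1 / 3)
})

test_that("adding an edge never decreases efficiency or lengthens paths", {
  set.seed(27)
  for (i in 1:10) {
    A <- random_adjacency(10, 0.2)
    off <- which(!A & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    B <- A; B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- TRUE
    pA <- shortest_paths_matrix(net_from_adjacency(A))
    pB <- shortest_paths_matrix(net_from_adjacency(B))
    expect_true(all(pB <= pA))
    expect_gte(global_efficiency(pB), global_efficiency(pA))
  }
})

test_that("metrics are invariant under cell relabeling", {
  set.seed(28)
  A <- random_adjacency(12, 0.25)
  net <- net_from_adjacency(A)
  perm <- sample(12)
  netp <- net_from_adjacency(A[perm, perm])
  for (f in list(function(n) hub_fraction(n),
                 function(n) clustering_coefficient(n)$C_avg,
                 function(n) characteristic_path_length(shortest_paths_matrix(n)),
                 function(n) global_efficiency(shortest_paths_matrix(n)))) {
    expect_equal(f(net), f(netp))
  }
})

test_that("threshold calibration flags degenerate inputs and scans hub structure", {
  t0 <- sin(2 * pi * (1:200) / 40)
  same <- matrix(rep(t0, 12), 12, byrow = TRUE)
  expect_warning(cal <- calibrate_threshold(same, significance = FALSE),
                 "no candidate")
  expect_false(cal$qualified)
  expect_equal(cal$R_th, 0.95)

  # synchronized communities whose size spectrum makes the degree
  # histogram follow a power law: counts 40, 24, 16, 12, 9 at degrees
  # 1, 2, 3, 5, 8
  set.seed(29)
  Tn <- 150
  sizes <- c(rep(2, 20), rep(3, 8), rep(4, 4), rep(6, 2), 9)
  tr <- do.call(rbind, lapply(sizes, function(s) {
    g <- rnorm(Tn)
    t(vapply(seq_len(s), function(i) g + rnorm(Tn, sd = 0.05), numeric(Tn)))
  }))
  cal2 <- calibrate_threshold(tr, significance = TRUE)
  expect_true(cal2$qualified)
  row <- cal2$scan[cal2$scan$candidate == cal2$R_th, ]
  expect_gte(row$r_squared, 0.9)
  expect_gte(row$n_bins, 5)
  expect_true(all(diff(cal2$scan$mean_degree) <= 1e-12))
  # every retained link is far stronger than its circular-shift null
  expect_true(all(cal2$link_p >= 0 & cal2$link_p <= 1))
  expect_lt(median(cal2$link_p), 0.05)
})
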