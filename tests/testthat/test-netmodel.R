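test_that("the Discrimination Index follows its defining arithmetic", {
  mk <- function(cw, ccw, fw, bw)
    matrix(c(cw, ccw, fw, bw), 1, 4,
           dimnames = list("c", c("clockwise", "counterclockwise",
                                  "forward_translation",
                                  "backward_translation")))
  expect_equal(discrimination_index(mk(2, 2, 3, 1))$di, 1)
  expect_equal(discrimination_index(mk(3, 1, 2, 2))$di, -1)
  expect_equal(discrimination_index(mk(3, 1, 4, 2))$di, 0)
  deg <- discrimination_index(mk(1, 1, 2, 2))
  expect_equal(deg$di, 0)
  expect_true(deg$degenerate)
})

test_that("DI stays within [-1, 1] and is scale-invariant under fuzzing", {
  set.seed(8)
  for (i in 1:1000) {
    r <- matrix(rnorm(4, sd = 5), 1, 4,
                dimnames = list("c", c("clockwise", "counterclockwise",
                                       "forward_translation",
                                       "backward_translation")))
    di <- discrimination_index(r)$di
    expect_gte(di, -1)
    expect_lte(di, 1)
    k <- runif(1, 0.1, 9)
    expect_equal(discrimination_index(k * r)$di, di, tolerance = 1e-12)
  }
})

test_that("condition drives have the documented structure", {
  dr <- condition_drives()
  expect_equal(unname(rowSums(dr)), rep(2, 4))
  # forward is left-right symmetric
  expect_equal(dr["forward_translation", "sL_FtB"],
               dr["forward_translation", "sR_FtB"])
  # CW and CCW are mirror images (swap L and R)
  expect_equal(unname(dr["clockwise", c("sR_FtB", "sR_BtF")]),
               unname(dr["counterclockwise", c("sL_FtB", "sL_BtF")]))
})

test_that("a feedforward network returns its drive exactly", {
  cf <- network_config(g = 0)
  cf$W[] <- 0
  dr <- condition_drives()
  for (cd in rownames(dr)) {
    v <- solve_network(cf, dr[cd, ])
    expect_equal(unname(v), unname(as.numeric(cf$D %*% dr[cd, ])))
  }
})

test_that("the two-node gap toy matches the hand-solved system", {
  for (g in c(0.1, 0.5, 1, 5, 50)) {
    cf <- network_config(g = 0)
    cf$W[] <- 0; cf$D[] <- 0
    cf$D["HS_L", "sL_FtB"] <- 1
    cf$gap_edges <- data.frame(a = "HS_L", b = "H2_L", g = g)
    v <- solve_network(cf, c(1, 0, 0, 0))
    expect_equal(unname(v["HS_L"]), (1 + g) / (1 + 2 * g),
                 tolerance = 1e-12)
    expect_equal(unname(v["H2_L"]), g / (1 + 2 * g), tolerance = 1e-12)
    expect_equal(unname(sum(v[c("HS_L", "H2_L")])), 1, tolerance = 1e-12)
  }
  # g -> infinity: both nodes meet in the middle
  cf <- network_config(g = 0); cf$W[] <- 0; cf$D[] <- 0
  cf$D["HS_L", "sL_FtB"] <- 1
  cf$gap_edges <- data.frame(a = "HS_L", b = "H2_L", g = 1e6)
  v <- solve_network(cf, c(1, 0, 0, 0))
  expect_equal(unname(v[c("HS_L", "H2_L")]), c(0.5, 0.5), tolerance = 1e-4)
})

test_that("gap current is conserved across each edge", {
  cf <- network_config(g = 0.7)
  v <- solve_network(cf, condition_drives()["clockwise", ])
  for (k in seq_len(nrow(cf$gap_edges))) {
    a <- cf$gap_edges$a[k]; b <- cf$gap_edges$b[k]; g <- cf$gap_edges$g[k]
    expect_equal(g * (v[b] - v[a]) + g * (v[a] - v[b]), 0,
                 ignore_attr = TRUE)
  }
})

test_that("responses are left-right mirror symmetric", {
  r <- condition_responses(network_config())
  swap_cell <- function(cell) {
    if (grepl("_L$", cell)) sub("_L$", "_R", cell) else sub("_R$", "_L", cell)
  }
  swap_cond <- c(clockwise = "counterclockwise",
                 counterclockwise = "clockwise",
                 forward_translation = "forward_translation",
                 backward_translation = "backward_translation")
  for (cell in rownames(r)) for (cd in colnames(r)) {
    expect_equal(r[cell, cd], r[swap_cell(cell), swap_cond[[cd]]],
                 tolerance = 1e-12)
  }
})

test_that("perturbations act on the intended weights and are idempotent", {
  cf <- network_config()
  sh <- perturb(cf, "shakB")
  expect_true(all(sh$gap_edges$g == 0))
  expect_identical(sh$W, cf$W)
  expect_identical(perturb(sh, "shakB"), sh)
  h2 <- perturb(cf, "silence_H2_chem")
  expect_true(all(h2$W[, c("H2_L", "H2_R")] == 0))
  expect_identical(h2$gap_edges, cf$gap_edges)
  expect_identical(perturb(h2, "silence_H2_chem"), h2)
  kir <- perturb(cf, "kir_HS")
  expect_equal(nrow(kir$gap_edges), 0)
  expect_error(perturb(cf, "unknown"))
  # g = 0 reproduces the chemical-only model exactly
  cf0 <- cf; cf0$gap_edges$g <- 0
  expect_identical(condition_responses(cf0), condition_responses(sh))
})

test_that("an isolated HS with opponent drive has zero DI", {
  cf <- network_config(g = 0, w_ipsi_to_hs = 1)
  cf$W[] <- 0
  r <- condition_responses(cf)
  expect_equal(unname(r["HS_L", ]), c(-1, 1, 1, -1))
  expect_equal(discrimination_index(r)$di[1], 0)
})

test_that("DI decreases with gap conductance for every cell", {
  sw <- di_vs_g_sweep(network_config(), seq(0, 1, by = 0.1))
  expect_true(all(sw$ok))
  for (d in split(sw, sw$cell)) {
    v <- d$di[order(d$g)]
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(v[-1] < v[1]))   # strictly below the uncoupled value
  }
  # the g = 0 sweep point equals the shakB-perturbed model's DI
  cf <- network_config()
  di0 <- discrimination_index(condition_responses(perturb(cf, "shakB")))
  expect_equal(sw$di[sw$g == 0], di0$di, tolerance = 1e-12)
})

test_that("rectified dynamics converge and stay non-negative", {
  cfr <- network_config(rectify = TRUE)
  r <- condition_responses(cfr)
  expect_true(all(r >= 0))
  di <- discrimination_index(r)
  expect_true(all(di$di >= -1 & di$di <= 1))
})

test_that("configurations survive a JSON round trip", {
  cf <- network_config(g = 0.3)
  path <- tempfile(fileext = ".json")
  write_network_config(cf, path)
  cf2 <- read_network_config(path)
  expect_equal(condition_responses(cf2), condition_responses(cf),
               tolerance = 1e-12)
})
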