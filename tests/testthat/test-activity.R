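test_that("normalization: min-max, degenerate gene, quantile truncation", {
  expect_equal(as.vector(normalize_expression(cbind(g = c(0, 5, 10)),
                                              upper_quantile = 1)),
               c(0, 0.5, 1))
  expect_equal(as.vector(normalize_expression(cbind(g = c(7, 7, 7)))),
               c(0, 0, 0))
  # independent quantile-truncate-rescale oracle, coded differently
  v <- 0:100
  oracle <- local({
    hi <- unname(stats::quantile(v, 0.99))
    w <- ifelse(v > hi, hi, v)
    (w - min(w)) / (hi - min(w))
  })
  got <- as.vector(normalize_expression(cbind(g = as.numeric(v)),
                                        upper_quantile = 0.99))
  expect_equal(got, oracle)
  expect_true(all(got[v >= 100 * 0.99] == 1))
  expect_error(normalize_expression(cbind(g = c(-1, 2))), "non-negative")
})

test_that("node values aggregate bundled genes", {
  expr <- cbind(g1 = c(0.2, 0.4), g2 = c(0.8, 0.6), g3 = c(0.1, 0.9))
  rownames(expr) <- c("s1", "s2")
  circ <- circuit("c", list(R = "g1", M = c("g1", "g2"), E = c("g1", "g2", "g3")),
                  data.frame(from = c("R", "M"), to = c("M", "E"),
                             sign = "activation"), "R", "E")
  nv <- node_values(expr, circ)
  expect_equal(nv[, "R"], expr[, "g1"])           # single gene: identity
  expect_equal(unname(nv["s1", "M"]), 0.5)        # mean of 0.2, 0.8
  nv_min <- node_values(expr, circ, aggregator = "min")
  expect_equal(unname(nv_min[, "E"]),
               unname(apply(expr[, c("g1", "g2", "g3")], 1, min)))
  # missing-gene policy
  expr2 <- expr[, 1:2]
  expect_error(node_values(expr2, circ), "absent")
  expect_warning(nv_imp <- node_values(expr2, circ, missing_gene = "impute"),
                 "imputing")
  expect_equal(unname(nv_imp["s1", "E"]), mean(c(0.2, 0.8, 0.5)))
})

test_that("propagation matches the stated rule", {
  cc <- chain_circuit()
  sat <- matrix(1, 1, 3, dimnames = list("s", c("R", "M", "E")))
  expect_equal(unname(propagate_circuit(cc, sat)), 1)   # saturated chain
  zero <- sat; zero[1, 2] <- 0
  expect_equal(unname(propagate_circuit(cc, zero)), 0)  # absorbing zero
  # hand evaluation: v_E=0.8, two activating parents S=0.5, one inhibiting S=0.5
  cc2 <- circuit("h", list(A1 = "a", A2 = "b", I1 = "c", E = "e"),
                 data.frame(from = c("A1", "A2", "I1"), to = "E",
                            sign = c("activation", "activation", "inhibition")),
                 receptors = c("A1", "A2", "I1"), effector = "E")
  nv <- matrix(c(0.5, 0.5, 0.5, 0.8), 1, 4,
               dimnames = list("s", c("A1", "A2", "I1", "E")))
  expect_equal(unname(propagate_circuit(cc2, nv)), 0.3)
  expect_error(propagate_circuit(cc, sat * 2), "outside")
})

test_that("pure activation chains satisfy the product closed form exactly", {
  withr::with_seed(11, {
    for (L in c(2, 4, 7)) {
      genes <- setNames(paste0("g", 1:L), paste0("n", 1:L))
      cc <- circuit("ch", as.list(genes),
                    data.frame(from = names(genes)[-L], to = names(genes)[-1L],
                               sign = "activation"),
                    receptors = names(genes)[1L], effector = names(genes)[L])
      nv <- matrix(runif(3 * L), 3, L,
                   dimnames = list(paste0("s", 1:3), names(genes)))
      oracle <- apply(nv, 1, function(v) Reduce(`*`, v))
      expect_identical(unname(propagate_circuit(cc, nv)), unname(oracle))
    }
  })
})

test_that("activities: collection contract, range, determinism", {
  cfg <- small_sim_config(seed = 7)
  ds <- simulate_dataset(cfg)
  expr <- normalize_expression(ds$expr)
  Y <- compute_activities(ds$collection, expr)
  expect_identical(colnames(Y), names(collection_circuits(ds$collection)))
  expect_identical(rownames(Y), rownames(expr))
  expect_true(all(Y >= 0 & Y <= 1))
  # all genes at 1 -> all activities 1
  ones <- matrix(1, 2, ncol(expr), dimnames = list(c("a", "b"), colnames(expr)))
  expect_true(all(compute_activities(ds$collection, ones) == 1))
  # bit-identical on re-run
  ds2 <- simulate_dataset(small_sim_config(seed = 7))
  expect_identical(Y, compute_activities(ds2$collection,
                                         normalize_expression(ds2$expr)))
})

test_that("expression TSV round-trips", {
  expr <- matrix(c(0.125, 3.5, 2, 7.25), 2, 2,
                 dimnames = list(c("s1", "s2"), c("gA", "gB")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, f)
  back <- read_expression(f)
  expect_equal(back, expr)
})
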