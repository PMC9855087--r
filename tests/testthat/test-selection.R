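ranking100 <- setNames(seq(1, 0.01, length.out = 100), sprintf("g%03d", 1:100))

test_that("selection anchors from the convex rule", {
  # perfectly predicted circuit: top 5%
  s <- select_kdts(ranking100, r2 = 1)
  expect_length(s$selected_kdts, 5L)
  expect_identical(s$selected_kdts, names(ranking100)[1:5])
  # no predictability: nothing selected
  expect_length(select_kdts(ranking100, r2 = 0)$selected_kdts, 0L)
  expect_length(select_kdts(ranking100, r2 = -2)$selected_kdts, 0L)
  # n_kdts=40, r2=0.5 -> fraction 0.025 -> floor(1.0) = 1 gene
  r40 <- setNames(runif(40), sprintf("h%02d", 1:40))
  s40 <- select_kdts(r40, r2 = 0.5)
  expect_equal(s40$selected_fraction, 0.025)
  expect_length(s40$selected_kdts, 1L)
  expect_identical(s40$selected_kdts, names(which.max(r40)))
})

test_that("selection is monotone in r2 and bounded", {
  grid <- seq(0, 1, by = 0.05)
  prev <- character()
  for (r2 in grid) {
    cur <- select_kdts(ranking100, r2)$selected_kdts
    expect_true(all(prev %in% cur)) # subset property along increasing r2
    expect_lte(length(cur), ceiling(0.05 * 100))
    prev <- cur
  }
})

test_that("ties break by score descending then symbol ascending", {
  r <- setNames(c(rep(0.5, 10), rep(0.1, 30)), sprintf("t%02d", 40:1))
  s <- select_kdts(r, r2 = 1) # 2 genes
  expect_identical(s$selected_kdts, c("t31", "t32"))
  expect_identical(select_kdts(r, r2 = 1)$selected_kdts, s$selected_kdts)
})

test_that("gamma exponent shrinks selection for imperfect circuits", {
  expect_length(select_kdts(ranking100, 0.6, gamma = 1)$selected_kdts, 3L)
  expect_length(select_kdts(ranking100, 0.6, gamma = 3)$selected_kdts, 1L)
  # at r2 = 1 gamma is irrelevant
  expect_length(select_kdts(ranking100, 1, gamma = 3)$selected_kdts, 5L)
})

test_that("selection guards its inputs", {
  expect_error(select_kdts(setNames(numeric(), character()), 1), "empty")
  expect_error(select_kdts(ranking100, NaN), "non-finite")
  expect_error(select_kdts(-ranking100, 1), "non-negative")
})

test_that("circuits_per_target matches independent set algebra", {
  sels <- list(
    structure(list(circuit_id = "c1", r2 = 1, selected_fraction = 0.05,
                   selected_kdts = c("gA", "gB")), class = "kdt_circuit_selection"),
    structure(list(circuit_id = "c2", r2 = 1, selected_fraction = 0.05,
                   selected_kdts = c("gA")), class = "kdt_circuit_selection"),
    structure(list(circuit_id = "c3", r2 = 0, selected_fraction = 0,
                   selected_kdts = character()), class = "kdt_circuit_selection"))
  pmap <- c(c1 = "P1", c2 = "P1", c3 = "P2")
  out <- circuits_per_target(sels, c("gA", "gB", "gC"), pmap)
  expect_equal(out$per_kdt$n_circuits, c(2L, 1L, 0L))
  expect_equal(out$per_kdt$n_pathways, c(1L, 1L, 0L))
  expect_equal(out$shared["gA", "gB"], 1)   # both in c1 only
  expect_equal(out$shared["gA", "gA"], 2)
  expect_equal(out$shared["gB", "gC"], 0)
  # independent recomputation from the table
  tab <- setNames(lapply(sels, `[[`, "selected_kdts"),
                  vapply(sels, `[[`, "", "circuit_id"))
  for (g in c("gA", "gB", "gC"))
    expect_equal(out$per_kdt$n_circuits[out$per_kdt$gene == g],
                 sum(vapply(tab, function(s) g %in% s, TRUE)))
})

test_that("selection over a relevance matrix keeps circuit alignment", {
  rel <- matrix(runif(20), 5, 4, dimnames = list(paste0("g", 1:5),
                                                 paste0("c", 1:4)))
  r2 <- setNames(c(1, 0.5, 0, -1), paste0("c", 1:4))
  sel <- select_all_circuits(rel, r2)
  expect_named(sel, paste0("c", 1:4))
  expect_identical(vapply(sel, `[[`, "", "circuit_id"), setNames(paste0("c", 1:4), paste0("c", 1:4)))
  expect_length(sel$c4$selected_kdts, 0L)
})
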