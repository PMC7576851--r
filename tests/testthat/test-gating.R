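test_that("point-in-polygon: interior, exterior and boundary conventions", {
  sq <- gate("sq", "iba1", "moi", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  tbl <- data.frame(
    case_id = "c", cell_id = 1:5, area_px = 1, area_um2 = 1,
    centroid_row = 0, centroid_col = 0,
    mean_iba1 = c(0.5, 2, 1, 0, 0.5),
    mean_moi = c(0.5, 2, 0.5, 0, 0)
  )
  out <- apply_gates(tbl, sq)
  # interior in; exterior out; edge points and vertices count as inside
  expect_identical(out$gate, c("sq", "ungated", "sq", "sq", "sq"))
})

test_that("gate membership is invariant to vertex rotation and orientation", {
  v <- rbind(c(0, 0), c(4, 1), c(5, 4), c(2, 6), c(-1, 3))
  set.seed(2)
  pts <- data.frame(
    case_id = "c", cell_id = 1:400, area_px = 1, area_um2 = 1,
    centroid_row = 0, centroid_col = 0,
    mean_iba1 = runif(400, -2, 6), mean_moi = runif(400, -1, 7)
  )
  base <- apply_gates(pts, gate("g", "iba1", "moi", v))$gate
  for (shift in 1:4) {
    rot <- v[c((shift + 1):5, 1:shift), ]
    expect_identical(apply_gates(pts, gate("g", "iba1", "moi", rot))$gate, base)
  }
  expect_identical(apply_gates(pts, gate("g", "iba1", "moi", v[5:1, ]))$gate, base)
})

test_that("even-odd containment agrees with an independent polygon routine", {
  skip_if_not_installed("mgcv")
  set.seed(8)
  for (rep in 1:5) {
    # random star-shaped polygon (simple by construction)
    k <- sample(5:9, 1)
    th <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 1, 4)
    v <- cbind(r * cos(th), r * sin(th))
    px <- runif(300, -4, 4); py <- runif(300, -4, 4)
    got <- histoflow:::point_in_polygon(px, py, v[, 1], v[, 2])
    bnd <- rbind(v, v[1, ])
    want <- mgcv::in.out(bnd, cbind(px, py))
    # the oracle's boundary convention may differ; compare clearly-off-boundary points
    d_edge <- vapply(seq_along(px), function(i) {
      min(vapply(seq_len(k), function(j) {
        j2 <- j %% k + 1
        a <- v[j, ]; b <- v[j2, ]
        t <- pmin(pmax(sum((c(px[i], py[i]) - a) * (b - a)) / sum((b - a)^2), 0), 1)
        sqrt(sum((c(px[i], py[i]) - (a + t * (b - a)))^2))
      }, numeric(1)))
    }, numeric(1))
    keep <- d_edge > 1e-6
    expect_identical(got[keep], want[keep])
  }
})

test_that("self-intersecting polygons and overlapping gates are rejected", {
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(gate("bow", "a", "b", bow), "self-intersecting")
  g1 <- rect_gate("g1", "a", "b", c(0, 2), c(0, 2))
  g2 <- rect_gate("g2", "a", "b", c(1, 3), c(1, 3))
  expect_error(gate_set(g1, g2), "overlap")
  # disjoint gates are fine
  g3 <- rect_gate("g3", "a", "b", c(5, 6), c(0, 2))
  expect_silent(gate_set(g1, g3))
})

test_that("a cell claimed by two gates on different axis pairs is an error naming both", {
  tbl <- data.frame(
    case_id = "c", cell_id = 1L, area_px = 1, area_um2 = 1,
    centroid_row = 0, centroid_col = 0,
    mean_iba1 = 1, mean_moi = 1, mean_lferritin = 1
  )
  g1 <- rect_gate("ab", "iba1", "moi", c(0, 2), c(0, 2))
  g2 <- rect_gate("ac", "iba1", "lferritin", c(0, 2), c(0, 2))
  expect_error(apply_gates(tbl, gate_set(g1, g2)), "'ab' and 'ac'")
})

test_that("true-boundary gates recover the generated population counts exactly", {
  case <- generate_case(small_case_config(seed = 42, n_cells = 120, n_plaques = 0))
  seg <- segment_and_measure(case)
  out <- apply_gates(seg$table, default_truth_gates())
  got <- table(out$gate)
  want <- table(case$truth$cells$population)
  for (pop in names(want)) {
    expect_equal(unname(got[[default_pop_to_gate[[pop]]]]), unname(want[[pop]]))
  }
})

test_that("population proportions are count ratios plus the ungated remainder", {
  tbl <- data.frame(
    case_id = "c", cell_id = 1:10, area_px = 1, area_um2 = 1,
    centroid_row = 0, centroid_col = 0,
    mean_iba1 = c(rep(0.5, 2), rep(2.5, 3), rep(4.5, 5)),
    mean_moi = 0.5
  )
  gs <- gate_set(
    rect_gate("A", "iba1", "moi", c(0, 1), c(0, 1)),
    rect_gate("B", "iba1", "moi", c(2, 3), c(0, 1)),
    rect_gate("C", "iba1", "moi", c(4, 5), c(0, 1))
  )
  pp <- population_proportions(apply_gates(tbl, gs))
  expect_equal(pp$proportion[match(c("A", "B", "C"), pp$population)],
               c(0.2, 0.3, 0.5))
  expect_equal(sum(pp$proportion), 1)
  # all cells in one gate -> proportion 1
  one <- apply_gates(tbl[1:2, ], gate_set(rect_gate("A", "iba1", "moi", c(0, 1), c(0, 1))))
  expect_equal(population_proportions(one)$proportion[1], 1)
  # zero cells -> empty summary, not an error
  expect_equal(nrow(population_proportions(apply_gates(tbl[0, ], gs))), 0L)
})

test_that("pooling preserves rows and case identity, and gating commutes with it", {
  c1 <- generate_case(small_case_config(seed = 51, n_cells = 25, n_plaques = 0))
  c2 <- generate_case(small_case_config(seed = 52, n_cells = 35, n_plaques = 0))
  t1 <- segment_and_measure(c1)$table; t1$case_id <- "case1"
  t2 <- segment_and_measure(c2)$table; t2$case_id <- "case2"
  expect_identical(pool_cases(list(t1)), t1)
  pooled <- pool_cases(list(t1, t2))
  expect_equal(nrow(pooled), nrow(t1) + nrow(t2))
  expect_equal(unname(table(pooled$case_id)["case1"]), nrow(t1))
  gs <- default_truth_gates()
  ap <- apply_gates(pooled, gs)
  for (cid in c("case1", "case2")) {
    per_case <- population_proportions(apply_gates(if (cid == "case1") t1 else t2, gs))
    from_pool <- population_proportions(ap[ap$case_id == cid, ])
    m <- match(per_case$population, from_pool$population)
    expect_equal(from_pool$proportion[m], per_case$proportion)
  }
  t3 <- t1[, setdiff(names(t1), "mean_moi")]
  expect_error(pool_cases(list(t1, t3)), "channels")
})

test_that("hierarchical gating nests correctly and degenerates to flat gating", {
  pops <- list(
    sim_population("low_lf_moihigh", 0.3, iba1 = c(log(30), 0.15),
                   lferritin = c(log(100), 0.15), moi = c(log(100), 0.15)),
    sim_population("low_lf_moilow", 0.3, iba1 = c(log(30), 0.15),
                   lferritin = c(log(100), 0.15), moi = c(log(20), 0.15)),
    sim_population("high_iba1", 0.4, iba1 = c(log(120), 0.15),
                   lferritin = c(log(20), 0.15), moi = c(log(20), 0.15))
  )
  case <- generate_case(small_case_config(seed = 61, n_cells = 150, n_plaques = 0,
                                          populations = pops))
  seg <- segment_and_measure(case, channels = c("iba1", "lferritin", "moi"))
  stage1 <- rect_gate("iba1low", "iba1", "lferritin", c(0, sqrt(30 * 120)), c(0, 4000))
  stage2 <- gate_set(
    rect_gate("lfhigh_moihigh", "moi", "lferritin", c(sqrt(20 * 100), 4000), c(0, 4000)),
    rect_gate("lfhigh_moilow", "moi", "lferritin", c(0, sqrt(20 * 100) - 1e-3), c(0, 4000))
  )
  hg <- hierarchical_gate(seg$table, stage1, stage2)
  truth <- case$truth$cells
  n_low <- sum(truth$population != "high_iba1")
  expect_equal(hg$stage1_n, n_low)
  p_high <- sum(truth$population == "low_lf_moihigh") / n_low
  got <- hg$summary$proportion[hg$summary$population == "lfhigh_moihigh"]
  expect_lt(abs(got - p_high), 3 * sqrt(p_high * (1 - p_high) / n_low))

  # stage1 admitting everything reduces to flat gating on the stage-2 axes
  all_gate <- rect_gate("all", "iba1", "lferritin", c(0, 4000), c(0, 4000))
  hg_all <- hierarchical_gate(seg$table, all_gate, stage2)
  flat <- population_proportions(apply_gates(seg$table, stage2))
  m <- match(hg_all$summary$population, flat$population)
  expect_equal(hg_all$summary$proportion, flat$proportion[m])

  # stage1 admitting nothing yields empty stage-2 summaries
  none <- rect_gate("none", "iba1", "lferritin", c(-10, -5), c(-10, -5))
  expect_equal(hierarchical_gate(seg$table, none, stage2)$stage1_n, 0L)
})

test_that("net-change heatmaps conserve mass and match a brute-force histogram", {
  c1 <- segment_and_measure(generate_case(small_case_config(seed = 71, n_cells = 60,
                                                            n_plaques = 0)))$table
  c2 <- segment_and_measure(generate_case(small_case_config(seed = 72, n_cells = 80,
                                                            n_plaques = 0)))$table
  # identical groups: exactly zero everywhere
  z <- net_change_heatmap(c1, c1, "iba1", "moi", bins = c(16L, 16L))
  expect_true(all(z == 0))
  h <- net_change_heatmap(c1, c2, "iba1", "moi", bins = c(16L, 16L))
  expect_lt(abs(sum(h)), 1e-9)
  # brute-force oracle over the same breaks
  bx <- attr(h, "x_breaks"); by <- attr(h, "y_breaks")
  brute <- function(tb) {
    m <- matrix(0, 16, 16)
    for (r in seq_len(nrow(tb))) {
      ix <- min(max(findInterval(tb$mean_iba1[r], bx, rightmost.closed = TRUE), 1), 16)
      iy <- min(max(findInterval(tb$mean_moi[r], by, rightmost.closed = TRUE), 1), 16)
      m[ix, iy] <- m[ix, iy] + 1
    }
    m / sum(m)
  }
  expect_equal(unclass(h), brute(c2) - brute(c1), ignore_attr = TRUE)
  expect_error(net_change_heatmap(c1[0, ], c2, "iba1", "moi"), "at least one cell")
})

test_that("quantile starter gates partition the pooled cloud without overlap", {
  tbl <- segment_and_measure(generate_case(small_case_config(seed = 81, n_cells = 100,
                                                             n_plaques = 0)))$table
  # split at the mixture fractions so the boundaries fall between clusters
  gs <- quantile_gates(tbl, "iba1", "moi", 0.2, 0.4)
  expect_s3_class(gs, "gate_set")
  out <- apply_gates(tbl, gs)  # would error if gates overlapped on a cell
  expect_true(all(out$gate %in% c(names(gs), "ungated")))
  expect_gt(mean(out$gate != "ungated"), 0.9)
})
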