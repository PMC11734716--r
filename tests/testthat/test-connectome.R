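# Synapse-table filtering, partner allocation and related reductions.

test_that("hand-computed toy allocation is reproduced exactly", {
  alloc <- allocate_partners(toy_synapse_table())
  # B->P1 (2 synapses) dropped by the per-connection filter; P3 (4) dropped
  # by the per-partner total filter; totals P1 = 12, P2 = 5 + 6 = 11
  expect_equal(alloc$post_id, c("P1", "P2"))
  expect_equal(alloc$total_synapses, c(12L, 11L))
  expect_equal(alloc$fraction, c(12 / 23, 11 / 23))
  expect_equal(alloc$rank, c(1L, 2L))
  expect_false("P3" %in% alloc$post_id)
})

test_that("degenerate tables yield empty allocations, not errors", {
  empty <- allocate_partners(toy_synapse_table()[0, ])
  expect_s3_class(empty, "partner_allocation")
  expect_equal(nrow(empty), 0L)
  # every connection below the per-connection threshold
  expect_equal(nrow(allocate_partners(toy_synapse_table(),
                                      min_per_connection = 20L)), 0L)
})

test_that("without filtering, fractions sum to 1 over all partners", {
  alloc <- allocate_partners(toy_synapse_table(), min_per_connection = 1L,
                             min_total = 1L)
  expect_equal(sort(alloc$post_id), c("P1", "P2", "P3"))
  expect_equal(sum(alloc$fraction), 1, tolerance = 1e-12)
  expect_equal(alloc$total_synapses[alloc$post_id == "P1"], 14L)
})

test_that("allocation is idempotent on its own retained synapses", {
  withr::with_seed(31, {
    tab <- synapse_table(data.frame(
      pre_id = sample(paste0("orn", 1:6), 600, replace = TRUE),
      pre_type = "ORNx",
      post_id = sample(paste0("P", 1:12), 600, replace = TRUE),
      x = rnorm(600), y = rnorm(600), z = rnorm(600)))
  })
  alloc <- allocate_partners(tab)
  conn <- stats::aggregate(list(n = rep(1L, nrow(tab))),
                           by = list(pre_id = tab$pre_id,
                                     post_id = tab$post_id), FUN = sum)
  keep_conn <- conn[conn$n >= 3L & conn$post_id %in% alloc$post_id, ]
  retained_rows <- paste(tab$pre_id, tab$post_id) %in%
    paste(keep_conn$pre_id, keep_conn$post_id)
  again <- allocate_partners(tab[retained_rows, ])
  expect_equal(again$post_id, alloc$post_id)
  expect_equal(again$total_synapses, alloc$total_synapses)
  expect_equal(again$fraction, alloc$fraction)
})

test_that("raising the total threshold never adds partners and fractions stay normalised", {
  withr::with_seed(17, {
    tab <- synapse_table(data.frame(
      pre_id = sample(paste0("orn", 1:5), 400, replace = TRUE),
      pre_type = "ORNx",
      post_id = sample(paste0("P", 1:10), 400, replace = TRUE),
      x = 0, y = 0, z = 0))
  })
  sizes <- vapply(c(1, 5, 10, 20, 40), function(mt)
    nrow(allocate_partners(tab, min_total = mt)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (mt in c(1, 10, 25)) {
    alloc <- allocate_partners(tab, min_total = mt)
    if (nrow(alloc)) {
      expect_equal(sum(alloc$fraction), 1, tolerance = 1e-12)
      expect_equal(alloc$rank, seq_len(nrow(alloc)))
      expect_true(all(diff(alloc$total_synapses) <= 0))
    }
  }
})

test_that("ties in totals are ranked by post id", {
  tab <- synapse_table(data.frame(
    pre_id = "A", pre_type = "ORNa",
    post_id = rep(c("Pb", "Pa"), each = 12), x = 0, y = 0, z = 0))
  alloc <- allocate_partners(tab)
  expect_equal(alloc$post_id, c("Pa", "Pb"))
})

test_that("prefilter normalisation uses the unfiltered synapse total", {
  alloc <- allocate_partners(toy_synapse_table(), normalize = "prefilter")
  expect_equal(alloc$fraction, c(12 / 29, 11 / 29))
})

test_that("mixed presynaptic types are rejected", {
  tab <- toy_synapse_table()
  tab$pre_type[1] <- "ORNb"
  expect_error(allocate_partners(tab), "single pre_type")
})

test_that("glomerulus assignment recovers planted spatial clusters", {
  spec <- do.call(rbind, lapply(1:3, function(g)
    data.frame(glomerulus = g, pre_id = paste0("orn", g), pre_type = "ORNx",
               post_id = paste0("P", g), n_synapses = 120L)))
  tab <- gen_synapse_table(spec, spread = 1, separation = 20, seed = 4)
  out <- assign_glomerulus(tab, n_clusters = 3, seed = 8)
  expect_equal(label_agreement(tab$glomerulus, out$cluster), 1)
  # closer blobs: agreement above 0.9 at five-spread separation
  tab5 <- gen_synapse_table(spec, spread = 1, separation = 5, seed = 4)
  out5 <- assign_glomerulus(tab5, n_clusters = 3, seed = 8)
  expect_gt(label_agreement(tab5$glomerulus, out5$cluster), 0.9)
})

test_that("glomerulus labels are stable under rigid motion of the frame", {
  spec <- data.frame(glomerulus = 1:2, pre_id = "o", pre_type = "ORNx",
                     post_id = c("P1", "P2"), n_synapses = 80L)
  tab <- gen_synapse_table(spec, spread = 1, separation = 12, seed = 2)
  out <- assign_glomerulus(tab, n_clusters = 2, seed = 6)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(tab[, c("x", "y", "z")]) %*% rot
  tab2 <- tab
  tab2[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 2), "+")
  out2 <- assign_glomerulus(tab2, n_clusters = 2, seed = 6)
  expect_equal(label_agreement(out$cluster, out2$cluster), 1)
})

test_that("single-cluster and degenerate coordinate cases behave", {
  tab <- toy_synapse_table()
  one <- assign_glomerulus(tab, n_clusters = 1)
  expect_true(all(one$cluster == 1L))
  flat <- tab
  flat$x <- 1; flat$y <- 2; flat$z <- 3
  expect_error(assign_glomerulus(flat, n_clusters = 2), "distinct")
})

test_that("report threshold matches a brute-force scan", {
  alloc <- data.frame(post_id = paste0("P", 1:5),
                      total_synapses = c(50L, 30L, 12L, 9L, 4L),
                      fraction = NA, rank = 1:5, retained = TRUE)
  expect_equal(estimate_report_threshold(alloc, 3), 9L)
  expect_equal(estimate_report_threshold(alloc, 0), 50L)
  expect_equal(estimate_report_threshold(alloc, 5), 0L)
  # brute force over random totals and observed counts
  withr::with_seed(23, {
    for (rep in 1:20) {
      totals <- sample(1:60, sample(3:8, 1), replace = TRUE)
      al <- data.frame(post_id = paste0("P", seq_along(totals)),
                       total_synapses = totals)
      obs <- sample(0:length(totals), 1)
      s_hat <- estimate_report_threshold(al, obs)
      brute <- min(which(vapply(0:max(totals), function(s)
        sum(totals > s) <= obs, logical(1)))) - 1L
      expect_equal(s_hat, brute)
      expect_lte(sum(totals > s_hat), obs)
    }
  })
  # monotone non-increasing in the observed partner count
  s_seq <- vapply(0:5, function(k) estimate_report_threshold(alloc, k),
                  integer(1))
  expect_true(all(diff(s_seq) <= 0))
})

test_that("class composition tabulates retained partners and sums to 100", {
  alloc <- allocate_partners(toy_synapse_table())
  cm <- data.frame(post_id = c("P1", "P2", "P3"),
                   post_class = c("uPN", "mPN", "LN"))
  comp <- class_composition(alloc, cm)
  expect_equal(sum(comp$percent), 100)
  expect_setequal(comp$post_class, c("uPN", "mPN"))
  expect_true(all(comp$n == 1L))
  # single class
  one <- class_composition(alloc, data.frame(post_id = c("P1", "P2"),
                                             post_class = "uPN"))
  expect_equal(one$percent, 100)
  # missing annotations fall back to "other"
  part <- class_composition(alloc, data.frame(post_id = "P1",
                                              post_class = "uPN"))
  expect_setequal(part$post_class, c("uPN", "other"))
  empty <- class_composition(allocate_partners(toy_synapse_table()[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("innervation symmetry index is antisymmetric and bounded", {
  expect_equal(innervation_symmetry(100, 100), 0)
  expect_equal(innervation_symmetry(100, 0), 50)
  expect_equal(innervation_symmetry(300, 100), 25)
  expect_equal(innervation_symmetry(100, 300), -25)
  withr::with_seed(3, {
    L <- runif(50, 0, 1000); R <- runif(50, 0, 1000)
    expect_equal(innervation_symmetry(L, R), -innervation_symmetry(R, L))
    expect_true(all(abs(innervation_symmetry(L, R)) <= 50))
  })
  expect_error(innervation_symmetry(0, 0), "undefined")
  expect_error(innervation_symmetry(-1, 5), "non-negative")
})

test_that("synapse tables and allocations round-trip through CSV", {
  tab <- toy_synapse_table()
  p1 <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), p1, row.names = FALSE)
  back <- read_synapse_csv(p1)
  expect_equal(nrow(back), nrow(tab))
  alloc <- allocate_partners(back)
  p2 <- tempfile(fileext = ".csv")
  write_allocation_csv(alloc, p2)
  alloc2 <- utils::read.csv(p2)
  expect_equal(alloc2$fraction, alloc$fraction, tolerance = 1e-12)
})
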