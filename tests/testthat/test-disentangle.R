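test_that("salient-event selection applies the stdev rule with signs", {
  proj <- matrix(0, 4, 4)
  proj[, 1] <- c(5, -4, 0.1, 0.1)
  pcs <- structure(
    list(eigenvalues = c(4, 3, 2, 1),
         components = diag(4),
         projections = proj,
         schema = structure(
           list(events = data.frame(attribute = paste0("a", 1:4),
                                    value = "v",
                                    key = paste0("a", 1:4, "=v"),
                                    attr_index = 1:4,
                                    stringsAsFactors = FALSE),
                attributes = paste0("a", 1:4),
                class_attribute = NA_character_, I = 4L),
           class = "event_schema"),
         center = FALSE),
    class = "pc_decomp")
  sel <- select_ars_on_pc(pcs, 1, stdev_factor = 1.0)
  # both extremes in, small ones out; opposite poles both reported
  expect_equal(sel$event, c("a1=v", "a2=v"))
  expect_equal(sel$pole, c(1, -1))
  # all-zero projections select nothing
  expect_equal(nrow(select_ars_on_pc(pcs, 2)), 0L)
})

test_that("cluster extraction finds connected components above threshold", {
  mk_rsrv <- function(mat, attrs) {
    keys <- paste0(attrs, "=v", seq_along(attrs))
    dimnames(mat) <- list(keys, keys)
    schema <- structure(
      list(events = data.frame(attribute = attrs,
                               value = paste0("v", seq_along(attrs)),
                               key = keys,
                               attr_index = as.integer(factor(attrs,
                                                              unique(attrs))),
                               stringsAsFactors = FALSE),
           attributes = unique(attrs), class_attribute = NA_character_,
           I = length(attrs)),
      class = "event_schema")
    structure(list(k = 1L, matrix = mat,
                   projection = rep(1, length(attrs)),
                   component = rep(1, length(attrs)),
                   threshold = 1.96, mode = "adjusted", schema = schema),
              class = "rsrv")
  }
  # one suprathreshold edge -> one 2-member cluster
  m1 <- matrix(0, 3, 3); m1[1, 2] <- m1[2, 1] <- 3.0
  out1 <- extract_clusters(mk_rsrv(m1, c("A1", "A2", "A3")))
  expect_length(out1$clusters, 1L)
  expect_equal(out1$clusters[[1]]$event, c("A1=v1", "A2=v2"))
  expect_equal(out1$edges$residual, 3.0)

  # transitivity: x-y and y-z suprathreshold, x-z below -> one 3-cluster
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 2.5
  m2[2, 3] <- m2[3, 2] <- -2.2
  m2[1, 3] <- m2[3, 1] <- 0.5
  out2 <- extract_clusters(mk_rsrv(m2, c("A1", "A2", "A3")))
  expect_length(out2$clusters, 1L)
  expect_setequal(out2$clusters[[1]]$event, c("A1=v1", "A2=v2", "A3=v3"))
  expect_equal(nrow(out2$edges), 2L)

  # zero matrix -> no clusters
  expect_length(extract_clusters(mk_rsrv(matrix(0, 3, 3),
                                         c("A1", "A2", "A3")))$clusters, 0L)

  # within-attribute entries never form edges
  m3 <- matrix(0, 3, 3); m3[1, 2] <- m3[2, 1] <- 5
  out3 <- extract_clusters(mk_rsrv(m3, c("A1", "A1", "A2")))
  expect_length(out3$clusters, 0L)
})

test_that("cluster edges are reproducible from the exported RSRV matrix", {
  synth <- generate_table2(8)
  res <- run_pipeline(synth$apc)
  for (cmp in res$components) {
    if (!nrow(cmp$edges)) next
    for (r in seq_len(nrow(cmp$edges))) {
      expect_equal(cmp$rsrv$matrix[cmp$edges$event_i[r],
                                   cmp$edges$event_j[r]],
                   cmp$edges$residual[r])
    }
    expect_true(all(abs(cmp$edges$residual) > res$srv$threshold))
    for (cl in cmp$clusters) expect_gte(nrow(cl), 2L)
  }
})

test_that("site filtering ranks associated sites above noise", {
  set.seed(21)
  m <- 120
  # one embedded associated pair (S1, S2) plus three noise sites
  s1 <- sample(c("a", "b"), m, TRUE)
  values <- data.frame(S1 = s1,
                       S2 = ifelse(s1 == "a", "x", "y"),
                       N1 = sample(letters[1:4], m, TRUE),
                       N2 = sample(letters[1:4], m, TRUE),
                       N3 = sample(letters[1:4], m, TRUE),
                       stringsAsFactors = FALSE)
  apc <- apc_table(values, sequence_ids = paste0("s", seq_len(m)))
  srv <- compute_srv(build_frequency_matrix(apc))
  kept <- filter_sites(srv, 2)
  expect_setequal(kept, c("S1", "S2"))
  # independent recomputation of the scores by a plain loop
  ev <- srv$schema$events
  scores <- sapply(unique(ev$attribute), function(site) {
    rows <- which(ev$attribute == site)
    tot <- 0
    for (i in rows) for (j in seq_len(nrow(ev))) tot <- tot + srv$sr[i, j]^2
    tot / length(rows)
  })
  expect_equal(names(sort(scores, decreasing = TRUE))[1:2], sort(kept))

  # constant site scores zero and is dropped first
  values$K <- "k"
  apc2 <- apc_table(values, sequence_ids = paste0("s", seq_len(m)))
  srv2 <- compute_srv(build_frequency_matrix(apc2))
  expect_false("K" %in% filter_sites(srv2, 5))
  # keep = site count returns everything (with a warning above it)
  expect_setequal(filter_sites(srv2, 6), c("S1", "S2", "N1", "N2", "N3", "K"))
  expect_warning(filter_sites(srv2, 7), "returning all")
})

test_that("pipeline chains all stages and exposes intermediates", {
  synth <- generate_table2(3)
  res <- run_pipeline(synth$apc)
  expect_s3_class(res, "disentangled_result")
  expect_gte(length(res$retained), 2L)
  expect_true(any(vapply(res$components,
                         function(c) length(c$clusters) >= 1, logical(1))))
  expect_equal(res$manifest$residual_mode, "adjusted")
  expect_equal(res$manifest$M, 300L)
  # class events participate
  expect_true(any(grepl("^Class=", res$schema$events$key)))

  # unsupervised run has no class events anywhere
  res0 <- run_pipeline(synth$apc, pipeline_config(use_class = FALSE))
  expect_false(any(grepl("^Class=", res0$schema$events$key)))

  # degenerate single-attribute table refused with stage tag
  one <- apc_table(data.frame(S1 = c("a", "b"), S2 = c("x", "y"),
                              stringsAsFactors = FALSE),
                   sequence_ids = c("s1", "s2"))
  one$values$S2 <- NULL
  one$site_labels <- "S1"
  one$attribute_kinds <- "categorical"
  expect_error(run_pipeline(one), "2 attributes")
})

test_that("significant_associations flattens and filters class pairs", {
  synth <- generate_table2(4)
  res <- run_pipeline(synth$apc)
  sig <- significant_associations(res)
  expect_true(all(c("component", "event_i", "event_j", "residual") %in%
                    names(sig)))
  ar <- significant_associations(res, ar_only = TRUE)
  expect_false(any(grepl("^Class=", c(ar$event_i, ar$event_j))))
  expect_lt(nrow(ar), nrow(sig))
})
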