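test_that("column counts count in-network anomalous edges once per column", {
  atlas <- synthetic_atlas(16)
  ids <- atlas$parcel_id
  net <- network_parcels(atlas, c("DMN", "CEN"))
  q <- net[1]
  hyper <- lapply(net[2:6], function(x) c(q, x))           # 5 in-network
  hypo <- list(c(net[2], net[3]))
  out_of_net <- setdiff(ids, net)[1]
  am <- manual_anomaly_matrix(ids, hyper = c(hyper, list(c(q, out_of_net))),
                              hypo = hypo)
  counts <- count_column_anomalies(am, atlas, c("DMN", "CEN"))
  expect_identical(counts$hyper_count[counts$parcel_id == q], 5L)
  expect_identical(counts$hypo_count[counts$parcel_id == q], 0L)
  # handshake lemma: totals sum to twice the flagged in-network edges
  expect_identical(sum(counts$total), 2L * (5L + 1L))
  # all-normal matrix gives all-zero counts
  am0 <- manual_anomaly_matrix(ids)
  expect_true(all(count_column_anomalies(am0, atlas)$total == 0L))
})

test_that("excluded edges never contribute to counts", {
  atlas <- synthetic_atlas(8)
  ids <- atlas$parcel_id
  net <- network_parcels(atlas, c("DMN", "CEN"))
  am <- manual_anomaly_matrix(ids,
                              hyper = list(c(net[1], net[2])),
                              excluded = list(c(net[1], net[3]),
                                              c(net[1], net[4])))
  counts <- count_column_anomalies(am, atlas)
  expect_identical(counts$total[counts$parcel_id == net[1]], 1L)
})

test_that("selection applies qualification, ranking, bias and tie-breaks", {
  counts <- data.frame(parcel_id = c("A", "B", "C"),
                       hyper_count = c(5L, 1L, 0L),
                       hypo_count = c(0L, 0L, 0L),
                       total = c(5L, 1L, 0L),
                       is_dlpfc = FALSE)
  expect_warning(pr <- select_targets(counts, min_anomalies = 2), "qualify")
  expect_identical(pr$targets$parcel_id, "A")
  # equal totals: the DLPFC parcel outranks under a 1.2 bias
  counts2 <- data.frame(parcel_id = c("X", "Y"),
                        hyper_count = c(3L, 3L), hypo_count = c(0L, 0L),
                        total = c(3L, 3L), is_dlpfc = c(FALSE, TRUE))
  pr2 <- select_targets(counts2, k_min = 1)
  expect_identical(pr2$targets$parcel_id[1], "Y")
  expect_equal(pr2$targets$biased_score[1], 3.6)
  # at most k_max targets, ranked by biased score
  counts3 <- data.frame(parcel_id = letters[1:5],
                        hyper_count = c(9L, 8L, 7L, 6L, 5L),
                        hypo_count = 0L, total = c(9L, 8L, 7L, 6L, 5L),
                        is_dlpfc = FALSE)
  expect_identical(select_targets(counts3)$targets$parcel_id, c("a", "b", "c"))
  # empty qualifying set: empty prescription with a warning
  expect_warning(pr0 <- select_targets(counts3, min_anomalies = 100))
  expect_identical(nrow(pr0$targets), 0L)
})

test_that("protocol assignment follows the hyper/hypo majority with cTBS ties", {
  expect_identical(assign_protocol(4, 1), "cTBS")
  expect_identical(assign_protocol(1, 4), "iTBS")
  expect_identical(assign_protocol(2, 2), "cTBS")
  expect_identical(assign_protocol(c(3, 0), c(1, 5)), c("cTBS", "iTBS"))
  expect_error(assign_protocol(0, 0), class = "agiletms_config_error")
})

test_that("selection is deterministic for identical inputs", {
  st <- small_study()
  pat <- generate_patient(st$cfg,
                          list(anomaly_spec("L_S001", "hyper", 4)),
                          seed = 55, parcel_ids = st$atlas$parcel_id,
                          reference = st$ref, model = st$model)
  am <- predict(st$model, embed_patient(pat$ts, st$ref))
  p1 <- suppressWarnings(select_targets(am, atlas = st$atlas))
  p2 <- suppressWarnings(select_targets(am, atlas = st$atlas))
  expect_identical(p1, p2)
})

test_that("a DMN-anomalous patient is prescribed cTBS at the injected parcels", {
  # mirrors the canonical two-target prescription: hyperconnected left 8Av
  # and left PGs treated with continuous theta-burst
  st <- calibration_study()
  atlas <- st$atlas
  atlas$parcel_id[atlas$parcel_id == "L_S005"] <- "L_8Av"
  atlas$is_dlpfc[atlas$parcel_id == "L_8Av"] <- TRUE
  atlas$parcel_id[atlas$parcel_id == "L_S013"] <- "L_PGs"
  ids <- atlas$parcel_id
  net <- network_parcels(atlas, c("DMN", "CEN"))
  # relabel the fitted study objects under the renamed parcels
  ref <- st$ref
  model <- st$model
  model$parcel_ids <- ids
  ref$g$parcel_ids <- ids
  pat <- generate_patient(st$cfg,
                          list(anomaly_spec("L_8Av", "hyper", 4, pool = net),
                               anomaly_spec("L_PGs", "hyper", 4, pool = net)),
                          seed = 314, parcel_ids = ids,
                          reference = ref, model = model)
  am <- predict(model, embed_patient(pat$ts, ref))
  pr <- select_targets(am, atlas = atlas)
  expect_true(all(c("L_8Av", "L_PGs") %in% pr$targets$parcel_id))
  expect_identical(unique(pr$targets$protocol[
    pr$targets$parcel_id %in% c("L_8Av", "L_PGs")]), "cTBS")
})
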