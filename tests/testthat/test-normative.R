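make_tangent <- function(values, ids) connectivity_matrix(values, "tangent", ids)

test_that("exclusion count is exactly round(E * fraction) with deterministic ties", {
  for (p in c(4L, 7L, 13L)) {
    e <- p * (p - 1L) / 2
    ids <- sprintf("p%02d", 1:p)
    set.seed(p)
    refs <- replicate(6, make_tangent(
      {m <- matrix(0, p, p); m[lower.tri(m)] <- rnorm(e); m + t(m)}, ids),
      simplify = FALSE)
    fit <- fit_normative(refs, exclusion_fraction = 1 / 3)
    expect_identical(sum(fit$excluded_mask), as.integer(round(e / 3)))
  }
  # ties at the cutoff: equal variances everywhere, first edges by index win
  ids <- c("a", "b", "c", "d")
  refs <- lapply(c(-1, 1), function(s)
    make_tangent({m <- matrix(0, 4, 4); m[lower.tri(m)] <- s; m + t(m)}, ids))
  fit <- fit_normative(refs)
  expect_identical(which(fit$excluded_mask), 1:2)   # round(6/3) = 2
})

test_that("identical reference matrices are a degenerate cohort", {
  ids <- c("a", "b", "c")
  m <- make_tangent(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3), ids)
  expect_error(fit_normative(list(m, m, m)),
               class = "agiletms_degenerate_error")
})

test_that("per-edge estimates recover iid standard normal edges", {
  p <- 10; e <- p * (p - 1) / 2; n <- 200L
  ids <- sprintf("p%02d", 1:p)
  set.seed(11)
  refs <- replicate(n, make_tangent(
    {m <- matrix(0, p, p); m[lower.tri(m)] <- rnorm(e); m + t(m)}, ids),
    simplify = FALSE)
  fit <- fit_normative(refs)
  tol <- 3 / sqrt(n)
  expect_lt(max(abs(fit$edge_mean)), 4 * tol)     # per-edge worst case
  expect_lt(abs(mean(fit$edge_mean)), tol)
  expect_lt(abs(mean(fit$edge_sd) - 1), tol)
  expect_identical(fit$n_reference, n)
})

test_that("scoring applies the 3-sigma rule edge-wise", {
  st <- small_study()
  model <- st$model
  p <- length(model$parcel_ids)
  # a patient lying exactly at the normative mean
  mean_mat <- matrix(0, p, p)
  mean_mat[lower.tri(mean_mat)] <- model$edge_mean
  mean_mat <- mean_mat + t(mean_mat)
  am0 <- predict(model, make_tangent(mean_mat, model$parcel_ids))
  expect_false(any(am0$status %in% c("hyper", "hypo")))
  # push one included edge 3.5 SDs up, another 3.5 down
  inc <- which(!model$excluded_mask)
  v <- model$edge_mean
  v[inc[1]] <- v[inc[1]] + 3.5 * model$edge_sd[inc[1]]
  v[inc[2]] <- v[inc[2]] - 3.5 * model$edge_sd[inc[2]]
  m <- matrix(0, p, p); m[lower.tri(m)] <- v; m <- m + t(m)
  am <- predict(model, make_tangent(m, model$parcel_ids))
  stv <- am$status[lower.tri(am$status)]
  expect_identical(stv[inc[1]], "hyper")
  expect_identical(stv[inc[2]], "hypo")
  expect_identical(sum(stv %in% c("hyper", "hypo")), 2L)
  # z and status agree everywhere; excluded edges carry no z
  zv <- am$z[lower.tri(am$z)]
  expect_true(all(is.na(zv[model$excluded_mask])))
  expect_identical(stv == "hyper", !is.na(zv) & zv > 3)
  expect_identical(am$status, t(am$status))
})

test_that("model-simulated null patients flag at the Gaussian tail rate", {
  st <- small_study()
  sims <- simulate(st$model, nsim = 30, seed = 123)
  rate <- mean(vapply(sims, function(s) {
    stv <- predict(st$model, s)$status
    stv <- stv[lower.tri(stv)]
    sum(stv %in% c("hyper", "hypo")) / sum(stv != "excluded")
  }, numeric(1)))
  expect_gt(rate, 0.0005)
  expect_lt(rate, 0.008)
})

test_that("anomaly reports restrict, order and conserve counts", {
  st <- small_study()
  pat <- generate_patient(st$cfg, list(), seed = 3,
                          parcel_ids = st$atlas$parcel_id)
  am <- predict(st$model, embed_patient(pat$ts, st$ref))
  rep <- anomaly_report(am, st$atlas, c("DMN", "CEN"))
  parcels <- network_parcels(st$atlas, c("DMN", "CEN"))
  expect_identical(dim(rep$status), c(length(parcels), length(parcels)))
  expect_identical(rownames(rep$status), parcels)
  # conservation against direct counting on the full matrix
  sub <- am$status[parcels, parcels]
  for (cat in c("normal", "hyper", "hypo", "excluded"))
    expect_identical(sum(rep$status == cat, na.rm = TRUE),
                     sum(sub == cat, na.rm = TRUE))
  expect_error(anomaly_report(am, st$atlas, "limbic"),
               class = "agiletms_atlas_error")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_anomaly_report(rep, path)
  back <- as.matrix(read.delim(path, row.names = 1))
  expect_identical(unname(back), unname(rep$status))
})

test_that("coef and summary expose the per-edge table", {
  st <- small_study()
  tab <- coef(st$model)
  e <- length(st$model$edge_mean)
  expect_identical(nrow(tab), e)
  expect_identical(sum(tab$excluded), sum(st$model$excluded_mask))
  expect_output(print(summary(st$model)), "Normative model")
})

test_that("normative models round-trip through JSON", {
  st <- small_study()
  path <- withr::local_tempfile(fileext = ".json")
  write_normative(st$model, path)
  back <- read_normative(path)
  expect_equal(back$edge_mean, st$model$edge_mean, tolerance = 1e-12)
  expect_identical(back$excluded_mask, st$model$excluded_mask)
  expect_identical(back$parcel_ids, st$model$parcel_ids)
  # a reloaded model scores identically
  pat <- generate_patient(st$cfg, list(), seed = 8,
                          parcel_ids = st$atlas$parcel_id)
  tan <- embed_patient(pat$ts, st$ref)
  expect_equal(predict(back, tan)$z, predict(st$model, tan)$z,
               tolerance = 1e-12)
})
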