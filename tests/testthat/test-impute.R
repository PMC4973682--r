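mcar_q2_cohort <- function(seed = 5, item_rate = 0.25, quest_rate = 0.2,
                           n_providers = 12, volume = 80) {
  co <- small_complete_cohort(seed = seed, n_providers = n_providers,
                              volume = volume)
  p <- co$patients
  set.seed(seed + 100)
  n <- nrow(p)
  drop_item <- stats::runif(n) < item_rate       # single-item non-response
  p$q2_item_3[drop_item] <- NA
  drop_q <- stats::runif(n) < quest_rate         # whole-questionnaire loss
  p[drop_q, paste0("q2_item_", 1:12)] <- NA
  p$y2_total <- ohs_total(p[, paste0("q2_item_", 1:12)])
  list(cohort = co, patients = p, drop_item = drop_item, drop_q = drop_q)
}

test_that("a dataset with nothing missing yields M identical copies", {
  co <- small_complete_cohort(seed = 3, n_providers = 6, volume = 25)
  set <- fit_and_impute(co$patients, co$providers, impute_spec("q2"),
                        M = 4, burn_in = 10, thin = 2, seed = 1)
  expect_s3_class(set, "imputation_set")
  expect_length(set$datasets, 4)
  for (d in set$datasets) expect_identical(d, co$patients)
  expect_identical(set$meta$note, "no missing values")
})

test_that("the chain emits exactly M datasets at the requested thinning", {
  co <- small_complete_cohort(seed = 8, n_providers = 4, volume = 15)
  p <- co$patients
  set.seed(1)
  p$q2_item_1[stats::runif(nrow(p)) < 0.3] <- NA
  p$y2_total <- ohs_total(p[, paste0("q2_item_", 1:12)])
  # the survey's production arithmetic: 100 draws, one every 100th iteration
  set <- fit_and_impute(p, co$providers, impute_spec("q2"),
                        M = 100, burn_in = 100, thin = 100, seed = 2)
  expect_length(set$datasets, 100)
  expect_length(set$states, 100)
})

test_that("observed cells are never altered and imputed cells are valid", {
  mc <- mcar_q2_cohort(seed = 5)
  set <- fit_and_impute(mc$patients, mc$cohort$providers, impute_spec("q2"),
                        M = 5, burn_in = 80, thin = 8, seed = 7)
  q2 <- paste0("q2_item_", 1:12)
  obs_mask <- !is.na(as.matrix(mc$patients[, q2]))
  for (d in set$datasets) {
    m <- as.matrix(d[, q2])
    expect_identical(m[obs_mask], as.matrix(mc$patients[, q2])[obs_mask])
    expect_false(anyNA(m))
    expect_true(all(m %in% 0:4))
  }
})

test_that("the imputation set is reproducible under a fixed seed", {
  mc <- mcar_q2_cohort(seed = 11, n_providers = 6, volume = 30)
  a <- fit_and_impute(mc$patients, mc$cohort$providers, impute_spec("q2"),
                      M = 3, burn_in = 40, thin = 4, seed = 42)
  b <- fit_and_impute(mc$patients, mc$cohort$providers, impute_spec("q2"),
                      M = 3, burn_in = 40, thin = 4, seed = 42)
  expect_identical(a$datasets, b$datasets)
})

test_that("MCAR-deleted item values are recovered in distribution", {
  mc <- mcar_q2_cohort(seed = 5, item_rate = 0.3, quest_rate = 0)
  set <- fit_and_impute(mc$patients, mc$cohort$providers, impute_spec("q2"),
                        M = 8, burn_in = 100, thin = 10, seed = 9)
  idx <- which(mc$drop_item)
  truth <- mc$cohort$truth$q2_item_3[idx]
  imputed <- unlist(lapply(set$datasets, function(d) d$q2_item_3[idx]))
  p_t <- prop.table(table(factor(truth, levels = 0:4)))
  p_i <- prop.table(table(factor(imputed, levels = 0:4)))
  expect_lt(max(abs(p_t - p_i)), 0.06)
  # and the imputed totals of whole-missing questionnaires track the truth
  mc2 <- mcar_q2_cohort(seed = 6, item_rate = 0, quest_rate = 0.25)
  set2 <- fit_and_impute(mc2$patients, mc2$cohort$providers, impute_spec("q2"),
                         M = 8, burn_in = 100, thin = 10, seed = 10)
  idx2 <- which(mc2$drop_q)
  true_mean <- mean(mc2$cohort$truth$y2_total[idx2])
  imp_mean <- mean(vapply(set2$datasets,
                          function(d) mean(d$y2_total[idx2]), numeric(1)))
  expect_lt(abs(imp_mean - true_mean), 1)
})

test_that("two-stage pipeline completes every modelled variable", {
  co <- generate_cohort(cohort_config(n_providers = 10, volume_mean = 60,
                                      mean_postop = 30, seed = 23))
  set <- impute_pipeline(co$patients, co$providers, M = 3,
                         burn_in = 60, thin = 6, burn_in_stage2 = 60, seed = 5)
  cols <- c(paste0("q1_item_", 1:12), paste0("q2_item_", 1:12),
            "ethnicity", "duration", "y1_total", "y2_total")
  for (d in set$datasets) {
    expect_false(anyNA(d[, cols]))
    expect_true(all(levels(d$ethnicity) == c("white", "nonwhite")))
    # totals are consistent with items
    expect_identical(d$y1_total, ohs_total(d[, paste0("q1_item_", 1:12)]))
  }
  # observed values identical across datasets
  obs <- !is.na(mc <- as.matrix(co$patients[, paste0("q1_item_", 1:12)]))
  for (d in set$datasets) {
    expect_identical(as.matrix(d[, paste0("q1_item_", 1:12)])[obs], mc[obs])
  }
})

test_that("Q2-only missingness takes the single-chain path and is complete", {
  mc <- mcar_q2_cohort(seed = 15, item_rate = 0, quest_rate = 0.3)
  set <- impute_pipeline(mc$patients, mc$cohort$providers, M = 4,
                         burn_in = 60, thin = 6, seed = 8)
  expect_identical(set$meta$pattern, "q1+q2")
  q1 <- paste0("q1_item_", 1:12)
  for (d in set$datasets) {
    expect_identical(d[, q1], mc$patients[, q1])  # stage 1 untouched
    expect_false(anyNA(d$y2_total))
  }
})

test_that("a provider with no observed outcomes is imputed near its case mix", {
  co <- small_complete_cohort(seed = 19, n_providers = 10, volume = 60)
  p <- co$patients
  target <- co$providers$provider_id[1]
  rows <- p$provider_id == target
  p[rows, paste0("q2_item_", 1:12)] <- NA
  p$y2_total <- ohs_total(p[, paste0("q2_item_", 1:12)])
  set <- fit_and_impute(p, co$providers, impute_spec("q2"),
                        M = 6, burn_in = 100, thin = 10, seed = 20)
  imp_mean <- mean(vapply(set$datasets,
                          function(d) mean(d$y2_total[rows]), numeric(1)))
  casemix <- mean(co$truth$casemix_mean[rows])
  # the provider effect is drawn from its prior, so the imputed mean sits at
  # the case-mix expectation (shrunk fully toward the overall mean)
  expect_lt(abs(imp_mean - casemix), 2)
})
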