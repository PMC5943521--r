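test_that("pathways recover exact inverse maps on noise-free chains", {
  tab <- exact_chain_table()
  # composite latent map: MM40 = c*(a*S + b) + d
  a <- 1.25; b <- 0.10; cc <- 0.95; dd <- -0.02
  true_slope <- cc * a
  true_int <- cc * b + dd
  inv_slope <- 1 / true_slope
  inv_int <- -true_int / true_slope

  for (v in c("1step-linear", "1step-deming", "2step-linear")) {
    f <- run_pathway(tab, v)
    expect_equal(f$transform$input_label, "MM40")
    expect_equal(f$transform$output_label, "S")
    expect_equal(f$transform$slope, inv_slope, tolerance = 1e-10)
    expect_equal(f$transform$intercept, inv_int, tolerance = 1e-10)
  }

  # one-step and two-step composites agree with each other to 1e-10
  f1 <- run_pathway(tab, "1step-linear")$transform
  f2 <- run_pathway(tab, "2step-linear")$transform
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
})

test_that("a table where the method already equals S yields the identity", {
  tab <- exact_chain_table()
  s <- tab[tab$method_label == "S", ]
  tab_id <- dplyr::bind_rows(
    tab[tab$method_label != "MM40", ],
    dplyr::mutate(s, method_label = "MM40"))
  # MM50 must also chain for the 2-step variant; rebuild MM50 = S too
  tab_id2 <- dplyr::bind_rows(s,
                              dplyr::mutate(s, method_label = "MM50"),
                              dplyr::mutate(s, method_label = "MM40"))
  for (v in c("1step-linear", "1step-deming", "2step-linear")) {
    f <- run_pathway(tab_id2, v)
    expect_equal(f$transform$slope, 1, tolerance = 1e-10)
    expect_equal(f$transform$intercept, 0, tolerance = 1e-10)
  }
  f <- run_pathway(tab_id, "1step-linear")
  expect_equal(f$transform$slope, 1, tolerance = 1e-10)
})

test_that("pathway fitting is invariant to subject order and duplication", {
  d <- generate_suvr_dataset(cohort_spec(seed = 8))
  tab <- d$table
  perm <- tab[sample(nrow(tab)), ]
  dup <- dplyr::distinct(dplyr::bind_rows(tab, tab[1:10, ]))
  for (v in c("1step-linear", "1step-deming", "2step-linear")) {
    t0 <- run_pathway(tab, v)$transform
    t1 <- run_pathway(perm, v)$transform
    t2 <- run_pathway(dup, v)$transform
    expect_equal(t1$slope, t0$slope, tolerance = 1e-12)
    expect_equal(t2$slope, t0$slope, tolerance = 1e-12)
    expect_equal(t1$intercept, t0$intercept, tolerance = 1e-12)
  }
  expect_error(run_pathway(tab[tab$method_label != "MM50", ],
                           "2step-linear"), "MM50")
})

test_that("pathway specs validate their chain structure", {
  sp <- pathway_spec("2step-linear")
  expect_equal(sp$source, "MM40")
  expect_equal(sp$standard, "S")
  expect_error(pathway_spec("bogus"), "unknown")
  expect_error(pathway_spec("broken",
                            steps = data.frame(response = c("A", "B"),
                                               predictor = c("B", "S"),
                                               method = "ridge")), "ols")
  expect_error(pathway_spec("broken",
                            steps = data.frame(response = c("A", "C"),
                                               predictor = c("B", "S"),
                                               method = "ols")), "chain")
  expect_error(pathway_spec("broken",
                            steps = data.frame(response = "A",
                                               predictor = "B",
                                               method = "ols")), "standard")
})

test_that("Centiloid conversion is the anchored affine map", {
  a <- centiloid_anchors(1.0095, 2.0761)
  expect_equal(suvr_to_centiloid(1.0095, a), 0)
  expect_equal(suvr_to_centiloid(2.0761, a), 100)
  expect_equal(suvr_to_centiloid((1.0095 + 2.0761) / 2, a), 50)
  # affine: CL of a transformed value is recoverable from transformed anchors
  tr <- linear_transform(1.4, -0.2)
  v <- c(1.1, 1.6, 2.2)
  a2 <- centiloid_anchors(apply_transform(invert_transform(tr), a$yc_mean),
                          apply_transform(invert_transform(tr), a$ad_mean))
  expect_equal(suvr_to_centiloid(apply_transform(invert_transform(tr), v), a2),
               suvr_to_centiloid(v, a), tolerance = 1e-10)
  expect_error(centiloid_anchors(2, 1), "ad_mean > yc_mean")
})

test_that("percent differences follow the reference-mean convention", {
  expect_equal(percent_difference(0, 1.5), 0)
  expect_equal(percent_difference(0.03, 1.5), 2)
  expect_error(percent_difference(0.1, 0), "positive")
})

test_that("evaluate_transform produces the group-mean report", {
  tab <- exact_chain_table()
  s <- tab[tab$method_label == "S", ]
  tab_id <- dplyr::bind_rows(s, dplyr::mutate(s, method_label = "MM40"))
  ident <- linear_transform(1, 0, "MM40", "S")
  rep0 <- evaluate_transform(tab_id, ident)
  expect_equal(rep0$group, c("YC", "AD"))
  expect_equal(rep0$mean_diff_suvr, c(0, 0))
  expect_equal(rep0$mean_pct_diff, c(0, 0))
  expect_equal(rep0$mean_cl_diff, c(0, 0))
  expect_true(all(rep0$pass))
  # group means at the anchors map to exactly 0 and 100 CL
  expect_equal(rep0$mean_cl, c(0, 100), tolerance = 1e-12)

  # a constructed 3% offset in the YC group fails with the YC row flagged
  bump <- dplyr::mutate(tab_id, suvr = ifelse(method_label == "MM40" &
                                                group == "YC",
                                              suvr * 1.03, suvr))
  anch <- anchors_from_table(tab_id)
  rep_bad <- evaluate_transform(bump, ident, anchors = anch)
  expect_false(rep_bad$pass[rep_bad$group == "YC"])
  expect_equal(rep_bad$mean_pct_diff[rep_bad$group == "YC"], 3,
               tolerance = 1e-10)

  # CL difference column equals SUVR difference scaled by the anchor span
  span <- anch$ad_mean - anch$yc_mean
  expect_equal(rep_bad$mean_cl_diff,
               rep_bad$mean_diff_suvr * 100 / span, tolerance = 1e-12)

  yc_only <- dplyr::filter(tab_id, group == "YC")
  expect_error(evaluate_transform(yc_only, ident, anchors = anch), "group")
})

test_that("the full calibration report has a zero reference row and a best variant", {
  d <- generate_suvr_dataset(cohort_spec(seed = 42))
  rep <- calibration_report(d$table)
  expect_s3_class(rep, "calibration_report")
  expect_equal(nrow(rep), 8)  # S + 3 variants, 2 groups each
  ref <- rep[rep$variant == "S", ]
  expect_equal(ref$mean_diff_suvr, c(0, 0))
  expect_equal(ref$mean_pct_diff, c(0, 0))
  expect_equal(ref$mean_cl, c(0, 100), tolerance = 1e-12)
  best <- attr(rep, "best_variant")
  expect_true(best %in% c("1step-linear", "1step-deming", "2step-linear"))
  worst <- tapply(abs(rep$mean_pct_diff[rep$variant != "S"]),
                  rep$variant[rep$variant != "S"], max)
  expect_equal(unname(worst[best]), min(worst))
  expect_output(print(rep), "Best variant")
})

test_that("level-1 replication check fits reimplementation vs reference", {
  d <- generate_suvr_dataset(cohort_spec(seed = 13))
  ref <- d$table[d$table$method_label == "S", ]
  # identical reimplementation: identity fit, passes any sane tolerance
  r1 <- level1_replication_check(ref, ref, slope_tol = 0.02,
                                 intercept_tol = 0.02, min_r2 = 0.98)
  expect_true(r1$pass)
  expect_equal(r1$fit$slope, 1, tolerance = 1e-12)
  expect_equal(r1$fit$intercept, 0, tolerance = 1e-12)
  expect_equal(r1$fit$r.squared, 1, tolerance = 1e-12)

  # tiny perturbation: near-identity; passes loose but not zero-slack tol
  set.seed(99)
  rei <- dplyr::mutate(ref, suvr = suvr + rnorm(dplyr::n(), 0, 0.001))
  r2 <- level1_replication_check(ref, rei, slope_tol = 0.05,
                                 intercept_tol = 0.05, min_r2 = 0.99)
  expect_true(r2$pass)
  r3 <- level1_replication_check(ref, rei, slope_tol = 0,
                                 intercept_tol = 0, min_r2 = 1)
  expect_false(r3$pass)

  expect_error(level1_replication_check(ref,
                                        dplyr::mutate(rei,
                                                      subject_id = paste0(
                                                        "X", subject_id)),
                                        0.1, 0.1, 0.9), "subject")
})
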