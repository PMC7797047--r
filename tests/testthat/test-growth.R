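mkSeries <- function(hours, f, depth, dph = 1) {
    data.frame(guide_id = "g", barcode = "b", hour = hours,
               generations = hours * dph, f = f, depth_sg = depth,
               depth_nc = 1000L)
}

test_that("relative frequency follows the log-ratio definition", {
    counts <- array(0L, dim = c(3, 1, 2),
                    dimnames = list(c("sg", "nc", "other"), "B1",
                                    c(0, 2)))
    counts["sg", 1, ] <- c(100L, 400L)
    counts["nc", 1, ] <- c(100L, 200L)
    counts["other", 1, ] <- c(50L, 50L)
    gc <- GuideCounts(counts, schedule_hours = c(0, 2))
    fr <- computeFrequency(gc, "nc", doublings_per_hour = 1)
    sg <- fr[fr$guide_id == "sg", ]
    expect_equal(sg$f[sg$hour == 2], 1)       # log2(400/200) - log2(1)
    expect_equal(sg$f[sg$hour == 0], 0)
    # the reference is identically zero
    expect_equal(fr$f[fr$guide_id == "nc"], c(0, 0))
    # generations rescaling
    expect_equal(unique(fr$generations), c(0, 2) * 1)
})

test_that("frequencies match a direct log-ratio oracle on random tensors", {
    set.seed(3)
    counts <- array(rpois(20 * 2 * 4, 500) + 1L, dim = c(20, 2, 4),
                    dimnames = list(sprintf("g%02d", 1:20),
                                    c("B1", "B2"), c(0, 2, 4, 6)))
    gc <- GuideCounts(counts, schedule_hours = c(0, 2, 4, 6))
    ref <- "g05"
    fr <- computeFrequency(gc, ref, doublings_per_hour = 0.94)
    for (k in sample(nrow(fr), 50)) {
        row <- fr[k, ]
        want <- log2(counts[row$guide_id, row$barcode,
                            as.character(row$hour)] /
                     counts[ref, row$barcode, as.character(row$hour)]) -
            log2(counts[row$guide_id, row$barcode, "0"] /
                 counts[ref, row$barcode, "0"])
        expect_equal(row$f, want, tolerance = 1e-12)
    }
})

test_that("growth fits truncate at the depth floor and match OLS", {
    # perfect line: slope recovered exactly, all points used
    fs <- mkSeries(c(0, 2, 4, 6, 10, 12, 14),
                   f = -0.5 * c(0, 2, 4, 6, 10, 12, 14), depth = 100L)
    fit <- fitRelativeGrowth(fs)
    expect_equal(fit$slope, -0.5)
    expect_equal(fit$r2, 1)
    expect_equal(fit$n_points_used, 7L)

    # the first sub-floor point is included, nothing after
    fs2 <- mkSeries(c(0, 2, 4, 6, 10, 12, 14), f = rnorm(7),
                    depth = c(100L, 80L, 60L, 9L, 50L, 40L, 30L))
    expect_equal(fitRelativeGrowth(fs2)$n_points_used, 4L)

    # a zero-count point truncates before itself
    fs3 <- mkSeries(c(0, 2, 4, 6), f = c(0, -1, NA, -3),
                    depth = c(100L, 50L, 0L, 25L))
    expect_equal(fitRelativeGrowth(fs3)$n_points_used, 2L)

    # under two usable points: no fit
    fs4 <- mkSeries(c(0, 2), f = c(0, NA), depth = c(100L, 0L))
    expect_null(fitRelativeGrowth(fs4))

    # noisy series against the normal-equations oracle
    set.seed(8)
    for (i in 1:20) {
        hours <- c(0, 2, 4, 6, 10, 12, 14)
        f <- -0.3 * hours + rnorm(7, 0, 0.2)
        f[1] <- 0
        fs5 <- mkSeries(hours, f, 1000L)
        fit5 <- fitRelativeGrowth(fs5)
        want <- oracleOls(hours, f)
        expect_equal(fit5$slope, want$slope, tolerance = 1e-10)
        expect_equal(fit5$intercept, want$intercept, tolerance = 1e-10)
    }
})

test_that("the reference negC is taken from the centre of the controls", {
    # three negC guides with engineered slopes -0.1, 0, +0.1
    hours <- c(0, 2, 4)
    mk <- function(slope) as.integer(round(1000 * 2^(slope * hours)))
    counts <- array(0L, dim = c(4, 1, 3),
                    dimnames = list(c("negC_a", "negC_b", "negC_c",
                                      "filler"), "B1", hours))
    counts["negC_a", 1, ] <- mk(-0.4)
    counts["negC_b", 1, ] <- mk(0)
    counts["negC_c", 1, ] <- mk(0.4)
    counts["filler", 1, ] <- 5000L
    gc <- GuideCounts(counts, schedule_hours = hours)
    ref <- pickReferenceNegc(gc, negc_ids = c("negC_a", "negC_b",
                                              "negC_c"),
                             doublings_per_hour = 1)
    expect_equal(ref, "negC_b")

    # identical trajectories: first id wins
    counts2 <- counts
    for (g in c("negC_a", "negC_b", "negC_c"))
        counts2[g, 1, ] <- 1000L
    gc2 <- GuideCounts(counts2, schedule_hours = hours)
    expect_equal(pickReferenceNegc(gc2, c("negC_a", "negC_b", "negC_c"),
                                   1), "negC_a")

    # all controls broken at some timepoint: error
    counts3 <- counts
    counts3[c("negC_a", "negC_b", "negC_c"), 1, 2] <- 0L
    gc3 <- GuideCounts(counts3, schedule_hours = hours)
    expect_error(pickReferenceNegc(gc3, c("negC_a", "negC_b", "negC_c"),
                                   1), "coverage")
})

test_that("escaper correction applies R2, Q-test and replicate filters", {
    # worked example: five consistent replicates plus one escaper
    fits <- data.frame(barcode = paste0("B", 1:6),
                       slope = c(-0.50, -0.52, -0.48, -0.51, -0.49,
                                 0.02),
                       r2 = 0.95)
    ec <- escaperCorrect(fits)
    expect_false(ec$rejected)
    expect_equal(ec$n_replicates, 5L)
    expect_equal(ec$removed$barcode, "B6")
    expect_equal(ec$removed$reason, "q_test")
    expect_equal(ec$mean_raw, mean(c(-0.50, -0.52, -0.48, -0.51,
                                     -0.49)))
    expect_equal(ec$sem, ec$sd / sqrt(5))
    # the hand-computed Dixon statistic behind that removal
    dq <- dixonQ(fits$slope)
    expect_equal(dq$q, 0.50 / 0.54, tolerance = 1e-12)
    expect_gt(dq$q, dixonQCritical(6))

    # fewer than three survivors: rejection, not an error
    few <- data.frame(barcode = c("B1", "B2", "B3"),
                      slope = c(-0.5, -0.5, -0.5), r2 = c(0.9, 0.2, 0.3))
    ec2 <- escaperCorrect(few)
    expect_true(ec2$rejected)
    expect_setequal(ec2$removed$reason[ec2$removed$barcode %in%
                                       c("B2", "B3")], "low_R2")

    # six identical slopes: nothing removed, SD zero
    same <- data.frame(barcode = paste0("B", 1:6), slope = -0.3,
                       r2 = 0.99)
    ec3 <- escaperCorrect(same)
    expect_equal(ec3$n_replicates, 6L)
    expect_equal(ec3$sd, 0)

    # near-zero slopes are exempt from the R2 filter
    flat <- data.frame(barcode = paste0("B", 1:4),
                       slope = c(0.02, -0.03, 0.01, 0.04), r2 = 0.1)
    ec4 <- escaperCorrect(flat)
    expect_false(ec4$rejected)
    expect_equal(ec4$n_replicates, 4L)

    # at most one replicate is ever removed by the Q test
    set.seed(13)
    for (i in 1:25) {
        f <- data.frame(barcode = paste0("B", 1:6),
                        slope = rnorm(6, -0.4, 0.3), r2 = 0.95)
        eci <- escaperCorrect(f)
        expect_lte(sum(eci$removed$reason == "q_test"), 1L)
    }
})

test_that("normalization maps the floor to 0 and the reference to 1", {
    expect_equal(normalizeGrowth(-1.23, -1.23), 0)
    expect_equal(normalizeGrowth(0, -1.23), 1)
    expect_equal(normalizeGrowth(-0.615, -1.23), 0.5)
    expect_error(normalizeGrowth(0.1, 1.23), "negative")
    # affine rescaling preserves ranking
    set.seed(2)
    raw <- rnorm(50, -0.5, 0.4)
    expect_equal(order(raw), order(normalizeGrowth(raw, -1.23)))
})

test_that("timecourse endpoint slopes behave on crafted series", {
    hours <- c(0, 2, 4, 6, 10)
    # exact line: every endpoint slope equals the all-points slope
    fs <- mkSeries(hours, f = -0.4 * hours, depth = 100L)
    tc <- timecourseGrowth(fs)
    expect_equal(unique(round(tc$slope, 12)), -0.4)
    # flat then declining: early endpoint slopes near zero, later negative
    fs2 <- mkSeries(hours, f = c(0, 0, 0, -1, -3), depth = 100L)
    tc2 <- timecourseGrowth(fs2)
    early <- tc2$slope[tc2$endpoint_hour %in% c(2, 4)]
    late <- tc2$slope[tc2$endpoint_hour %in% c(6, 10)]
    expect_true(all(abs(early) < 1e-12))
    expect_true(all(late < 0))
    # shallow endpoints are excluded
    fs3 <- mkSeries(hours, f = -0.1 * hours,
                    depth = c(100L, 100L, 5L, 100L, 100L))
    tc3 <- timecourseGrowth(fs3)
    expect_false(4 %in% tc3$endpoint_hour)
})

test_that("uncorrected pooled two-point slopes use no filtering", {
    counts <- array(0L, dim = c(2, 2, 3),
                    dimnames = list(c("sg", "nc"), c("B1", "B2"),
                                    c(0, 2, 4)))
    counts["sg", , ] <- rbind(c(100L, 50L, 25L), c(100L, 50L, 25L))
    counts["nc", , ] <- 200L
    gc <- GuideCounts(counts, schedule_hours = c(0, 2, 4))
    un <- uncorrectedGrowth(gc, "nc", doublings_per_hour = 1)
    expect_equal(un$slope[un$guide_id == "nc"], 0)
    # pooled: sg 200 -> 50, nc 400 -> 400 over 4 generations
    expect_equal(un$slope[un$guide_id == "sg"],
                 (log2(50 / 400) - log2(200 / 400)) / 4)
})

test_that("the full estimator recovers simulated growth rates", {
    truth <- tinyTruth()
    lib <- tinyLibrary()
    sim <- simulateCounts(truth, lib, "glucose", seed = 51)
    res <- suppressWarnings(
        estimateGrowth(sim$counts, doublings_per_hour = 0.94))
    v <- as.data.frame(guideVariants(lib))
    tn <- vapply(seq_len(nrow(v)), function(i)
        guideTruthGrowth(truth, v[i, ], "glucose"), numeric(1))
    m <- merge(res$estimates,
               data.frame(guide_id = v$guide_id, truth_norm = tn))
    expect_gt(nrow(m), 200)
    expect_gt(cor(m$normalized, m$truth_norm), 0.98)
    # every SEM follows from SD and replicate count
    expect_equal(res$estimates$sem,
                 res$estimates$sd / sqrt(res$estimates$n_replicates))
    # every removal has a recognized reason
    expect_true(all(res$removed$reason %in%
                    c("low_R2", "q_test", "too_few_replicates")))
})
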