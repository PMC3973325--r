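test_that("motifAdenines places the two strand adenines", {
    ad <- motifAdenines(100, 4000)
    expect_identical(ad$plus_pos, 101L)
    expect_identical(ad$minus_pos, 103L)
    # wrapping a circular junction
    adw <- motifAdenines(3998, 4000, circular = TRUE)
    expect_identical(adw$plus_pos, 3999L)
    expect_identical(adw$minus_pos, 1L)
    expect_error(motifAdenines(3998, 4000, circular = FALSE), "linear")
    # hand-enumerated 30-bp sequence with two sites
    s <- "AAGACTCAAAAAAAAAAGAGTCAAAAAAAA"
    occ <- scanMotif(s)
    expect_identical(occ, c(2L, 17L))
    ad2 <- motifAdenines(occ, nchar(s), circular = FALSE)
    expect_identical(ad2$plus_pos, c(3L, 18L))
    expect_identical(ad2$minus_pos, c(5L, 20L))
})

test_that("calibration derives the hemi-methylated midpoint", {
    ref <- data.frame(contig = "chr", position0 = 1:4, strand = "+",
                      ipd_ratio = c(7.5, 7.86, 7.6, 7.76), coverage = 50)
    model <- calibrate(ref)
    expect_equal(rFull(model), 7.68)
    expect_equal(rHemi(model), 4.34)
    expect_equal(tauThreshold(model), 2.4)
    # a flat unmethylated reference cannot calibrate
    flat <- transform(ref, ipd_ratio = 1)
    expect_error(calibrate(flat), "baseline")
    # coverage filter drops low-coverage rows
    mix <- rbind(ref, data.frame(contig = "chr", position0 = 9,
                                 strand = "+", ipd_ratio = 100,
                                 coverage = 1))
    expect_equal(rFull(calibrate(mix, minCoverage = 5)), 7.68)
    expect_error(calibrate(mix, minCoverage = 1000), "no reference")
})

test_that("calibration recovers the planted r_full from noisy kinetics", {
    plan <- syntheticPlan(seed = 14, genomeLength = 1e6, nGenes = 500,
                          nUnder = 0L, nAsym = 0L, ipdCv = 0.3,
                          coverageMean = 50)
    gen <- generateGenome(plan)
    expect_gt(nrow(gen$sites), 1500)
    mp <- generateMethylationPlan(plan, gen$sites)
    ref <- generateIpdDataset(plan, fullyMethylatedPlan(mp))
    model <- calibrate(ref)
    expect_lt(abs(rFull(model) - 7.68), 0.1)
})

test_that("methylated fraction inverts the two-state mixture", {
    m <- calibrationModel(7.68)
    expect_equal(methylatedFraction(7.68, m), 1)
    expect_equal(methylatedFraction(1, m), 0)
    # the 2.4 threshold corresponds to ~20% fully methylated or ~40%
    # hemi-methylated chromosomes
    expect_equal(methylatedFraction(2.4, m), 1.4 / 6.68)
    expect_equal(round(100 * methylatedFraction(2.4, m), -1), 20)
    expect_equal(hemiMethylatedFraction(2.4, m), 1.4 / 3.34)
    expect_equal(round(100 * hemiMethylatedFraction(2.4, m), -1), 40)
    # exact inverse consistency over a grid of fractions
    f <- seq(0, 1, by = 0.01)
    expect_equal(methylatedFraction(f * 7.68 + (1 - f), m), f)
    # monotone on [1, r_full], clipped outside
    r <- seq(0.5, 9, by = 0.1)
    fr <- methylatedFraction(r, m)
    expect_true(all(diff(fr[r >= 1 & r <= 7.68]) > 0))
    expect_true(all(fr >= 0 & fr <= 1))
    expect_equal(methylatedFraction(9, m), 1)
    expect_equal(methylatedFraction(0.5, m), 0)
    expect_lt(methylatedFraction(0.5, m, clip = FALSE), 0)
})

test_that("strand calls apply the strict threshold and coverage gate", {
    m <- calibrationModel(7.68)
    ad <- motifAdenines(c(0L, 10L, 20L, 30L), 1000, circular = FALSE)
    ipd <- data.frame(contig = "chr",
                      position0 = c(1, 3, 11, 13, 21, 23, 31, 33),
                      strand = rep(c("+", "-"), 4),
                      ipd_ratio = c(2.39, 2.40, 7.68, 7.68, 4.34, 4.34,
                                    5, 5),
                      coverage = c(50, 50, 50, 50, 50, 50, 0, 50))
    sc <- callStrands(ipd, ad, m)
    get <- function(site, st)
        sc$label[sc$site == site & sc$strand == st]
    expect_identical(get(0, "+"), "under_methylated")  # 2.39 < 2.4
    expect_identical(get(0, "-"), "methylated")        # 2.40, strict <
    expect_identical(get(10, "+"), "methylated")
    expect_identical(get(30, "+"), "no_data")          # coverage 0
    # absent adenine rows are no_data too
    ad2 <- motifAdenines(500L, 1000, circular = FALSE)
    sc2 <- callStrands(ipd, ad2, m)
    expect_true(all(sc2$label == "no_data"))
    # noiseless fractions 0 / 0.5 / 1 map to under / methylated / methylated
    ratios <- c(0, 0.5, 1) * 7.68 + (1 - c(0, 0.5, 1))
    ad3 <- motifAdenines(c(0L, 10L, 20L), 1000, circular = FALSE)
    ipd3 <- data.frame(contig = "chr", position0 = c(1, 11, 21),
                       strand = "+", ipd_ratio = ratios, coverage = 50)
    sc3 <- callStrands(ipd3, ad3, m)
    plus <- sc3[sc3$strand == "+", ]
    expect_identical(plus$label[order(plus$site)],
                     c("under_methylated", "methylated", "methylated"))
})

test_that("site classes combine the two strand labels", {
    m <- calibrationModel(7.68)
    ad <- motifAdenines(c(0L, 10L, 20L, 30L), 1000, circular = FALSE)
    ipd <- data.frame(contig = "chr",
                      position0 = c(1, 3, 11, 13, 21, 23, 31, 33),
                      strand = rep(c("+", "-"), 4),
                      ipd_ratio = c(1, 1, 1, 7, 7, 7.6, 7, 7),
                      coverage = c(50, 50, 50, 50, 50, 50, 2, 50))
    out <- callSites(callStrands(ipd, ad, m))
    lab <- setNames(out$calls$site_label, out$calls$site)
    expect_identical(unname(lab["0"]), "under_methylated")
    expect_identical(unname(lab["10"]), "asymmetric")
    expect_identical(unname(lab["20"]), "full")
    expect_identical(unname(lab["30"]), "no_data")
    expect_identical(unname(out$tally),
                     c(1L, 1L, 1L, 1L))
})

test_that("window profile rescales means onto the percent-full scale", {
    m <- calibrationModel(7.68)
    mk <- function(pos, ratio)
        data.frame(contig = "chr", position0 = pos, strand = "+",
                   ipd_ratio = ratio, coverage = 50)
    ipd <- mk(c(100, 5000, 25000, 47000), c(7.68, 7.68, 4.34, 6.01))
    prof <- windowProfile(ipd, m, window = 20000, chromLength = 60000)
    expect_equal(nrow(prof), 3)
    expect_equal(prof$percent_full[1], 100)   # mean 7.68
    expect_equal(prof$percent_full[2], 0)     # mean 4.34
    expect_equal(prof$percent_full[3], 50)    # mean 6.01
    expect_identical(prof$n_obs, c(2L, 1L, 1L))
    # tiling covers the chromosome once; observation counts add up
    expect_equal(prof$start, c(0, 20000, 40000))
    expect_equal(prof$end, c(20000, 40000, 60000))
    expect_equal(sum(prof$n_obs), nrow(ipd))
    # short final tile on a non-multiple length
    prof2 <- windowProfile(ipd, m, window = 20000, chromLength = 50000)
    expect_equal(prof2$end[3], 50000)
})

test_that("local-linear smoothing reproduces lines and damps noise", {
    mids <- seq(10000, 390000, by = 20000)
    lin <- data.frame(start = mids - 10000, end = mids + 10000,
                      midpoint = mids, n_obs = 5, mean_ratio = 5,
                      percent_full = 0.0005 * mids + 3)
    out <- smoothProfile(lin, span = 0.75, circular = FALSE)
    expect_lt(max(abs(out$smoothed_percent - lin$percent_full)), 1e-6)
    out2 <- smoothProfile(lin, span = 0.3, circular = FALSE)
    expect_lt(max(abs(out2$smoothed_percent - lin$percent_full)), 1e-6)
    # constant profile stays constant, also on the circle
    const <- transform(lin, percent_full = 42)
    outc <- smoothProfile(const, span = 0.75, circular = TRUE,
                          chromLength = 400000)
    expect_equal(outc$smoothed_percent, rep(42, nrow(const)))
    # fewer than 4 windows is an error
    expect_error(smoothProfile(lin[1:3, ], span = 0.75), "at least 4")
    # noisy sine on the circle: smoothing reduces the RMSE to the truth
    set.seed(99)
    L <- 4e5
    truth <- sin(2 * pi * mids / L)
    noisy <- transform(lin, percent_full = truth + rnorm(length(mids), 0, 1))
    sm <- smoothProfile(noisy, span = 0.75, circular = TRUE,
                        chromLength = L)
    rmse <- function(a, b) sqrt(mean((a - b)^2))
    expect_lt(rmse(sm$smoothed_percent, truth),
              rmse(noisy$percent_full, truth))
})

test_that("smoothing equals a direct weighted-least-squares oracle", {
    set.seed(7)
    mids <- seq(5000, 195000, by = 10000)
    y <- cos(2 * pi * mids / 2e5) + rnorm(length(mids), 0, 0.2)
    prof <- data.frame(start = mids - 5000, end = mids + 5000,
                       midpoint = mids, n_obs = 1, mean_ratio = 1,
                       percent_full = y)
    span <- 0.5
    sm <- smoothProfile(prof, span = span, circular = FALSE)
    n <- length(mids)
    q <- max(4L, ceiling(span * n))
    for (i in c(1, 5, 10, 15, 20)) {
        d <- abs(mids - mids[i])
        o <- order(d)[seq_len(q)]
        w <- (1 - pmin(1, d[o] / max(d[o]))^3)^3
        w[w <= 0] <- 1e-9
        fit <- lm(y[o] ~ I(mids[o] - mids[i]), weights = w)
        expect_equal(sm$smoothed_percent[i], unname(coef(fit)[1]),
                     tolerance = 1e-8)
    }
})

test_that("origin gradient statistic detects the planted gradient", {
    plan <- smallPlan(seed = 15)
    gen <- generateGenome(plan)
    mp <- generateMethylationPlan(plan, gen$sites)
    ipd <- generateIpdDataset(plan, mp)
    ref <- generateIpdDataset(plan, fullyMethylatedPlan(mp),
                              seedOffset = 1000L)
    model <- calibrate(ref)
    ad <- motifAdenines(gen$sites$position0, length(gen$genome))
    out <- callSites(callStrands(ipd, ad, model))
    set.seed(1)
    g <- originGradientStat(out$calls, 0, length(gen$genome),
                            nPerm = 2000)
    expect_gt(g$rho, 0)
    expect_lt(g$p_value, 0.01)
    # reversed gradient flips the sign
    rev <- smallPlan(seed = 15, gradient = c(0.1, 0.8))
    mpr <- generateMethylationPlan(rev, gen$sites)
    ipdr <- generateIpdDataset(rev, mpr)
    outr <- callSites(callStrands(ipdr, ad, model))
    set.seed(1)
    gr <- originGradientStat(outr$calls, 0, length(gen$genome),
                             nPerm = 500)
    expect_lt(gr$rho, 0)
    # all fractions equal: rho defined as 0
    tied <- out$calls
    tied$f_site <- 0.5
    gt <- originGradientStat(tied, 0, length(gen$genome), nPerm = 10)
    expect_equal(gt$rho, 0)
})

test_that("planted strand fractions are recovered within tolerance", {
    plan <- syntheticPlan(seed = 16, genomeLength = 3e5, nGenes = 150,
                          nUnder = 10L, nAsym = 5L, ipdCv = 0.3,
                          coverageMean = 50)
    gen <- generateGenome(plan)
    expect_gt(nrow(gen$sites), 500)
    mp <- generateMethylationPlan(plan, gen$sites)
    ipd <- generateIpdDataset(plan, mp)
    ref <- generateIpdDataset(plan, fullyMethylatedPlan(mp),
                              seedOffset = 1000L)
    model <- calibrate(ref)
    ad <- motifAdenines(gen$sites$position0, length(gen$genome))
    out <- callSites(callStrands(ipd, ad, model))
    truth <- (mp$f_plus + mp$f_minus) / 2
    est <- out$calls$f_site[match(mp$position0, out$calls$site)]
    mae <- mean(abs(est - truth), na.rm = TRUE)
    expect_lte(mae, 0.05)
})
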