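test_that("classifyDE applies strict thresholds and set inclusions", {
    stats <- data.frame(
        gene_id = c("ftsZ", "edge", "weak", "up1", "null"),
        log_ratio = c(-1.44, -2, -0.99, 1.2, 0.1),
        p_raw = c(1e-4, 0.005, 1e-3, 1e-4, 0.5),
        p_adj = c(1e-3, 0.01, 5e-3, 1e-3, 0.9))
    cls <- classifyDE(stats)
    # ftsZ-like gene: significant, down and strong_down
    expect_true("ftsZ" %in% significantGenes(cls))
    expect_true("ftsZ" %in% downGenes(cls))
    expect_true("ftsZ" %in% strongDownGenes(cls))
    # p_adj exactly at alpha is not significant (strict <)
    expect_false("edge" %in% significantGenes(cls))
    # |log2 ratio| just under 1 is down but not strong at 2-fold
    expect_true("weak" %in% downGenes(cls))
    expect_false("weak" %in% strongDownGenes(cls))
    expect_true("up1" %in% upGenes(cls))
    # inclusion chain strong %in% up/down %in% significant %in% universe
    expect_true(all(strongDownGenes(cls) %in% downGenes(cls)))
    expect_true(all(downGenes(cls) %in% significantGenes(cls)))
    expect_true(all(significantGenes(cls) %in% deUniverse(cls)))
    expect_length(intersect(upGenes(cls), downGenes(cls)), 0)
})

test_that("classifyDE inclusion invariants hold on random inputs", {
    set.seed(30)
    for (i in 1:20) {
        n <- sample(20:200, 1)
        p <- runif(n)
        stats <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                            log_ratio = rnorm(n, 0, 1.2),
                            p_raw = p, p_adj = p.adjust(p, "BH"))
        cls <- classifyDE(stats, alpha = 0.3)
        expect_true(all(c(strongUpGenes(cls), strongDownGenes(cls)) %in%
                            significantGenes(cls)))
        expect_identical(sort(union(upGenes(cls), downGenes(cls))),
                         sort(significantGenes(cls)[
                             abs(stats$log_ratio[match(
                                 significantGenes(cls),
                                 stats$gene_id)]) > 0]))
    }
})

test_that("simpleDE computes Welch statistics and BH adjustment", {
    set.seed(31)
    # identical groups give log_ratio 0 and p 1
    mat <- matrix(rep(c(5, 6, 7), each = 2), nrow = 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
    mat <- cbind(mat, mat)
    st <- simpleDE(mat, c("wt", "wt", "mut", "mut"), reference = "wt")
    expect_equal(st$log_ratio, c(0, 0, 0))
    expect_equal(st$p_raw, c(1, 1, 1))
    # agrees with t.test gene by gene
    m2 <- matrix(rnorm(50 * 6), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
    m2[1:10, 4:6] <- m2[1:10, 4:6] + 2
    g <- c("wt", "wt", "wt", "mut", "mut", "mut")
    st2 <- simpleDE(m2, g, reference = "wt")
    for (i in c(1, 7, 25, 50)) {
        tt <- t.test(m2[i, 4:6], m2[i, 1:3])
        expect_equal(st2$p_raw[i], tt$p.value, tolerance = 1e-10)
        expect_equal(st2$log_ratio[i],
                     unname(diff(rev(tt$estimate))), tolerance = 1e-10)
    }
    # planted effect of 2 recovered within +/- 0.3 at noise SD 0.1
    m3 <- matrix(rnorm(10 * 6, sd = 0.1), nrow = 10,
                 dimnames = list(sprintf("h%02d", 1:10), NULL))
    m3[, 4:6] <- m3[, 4:6] + 2
    st3 <- simpleDE(m3, g, reference = "wt")
    expect_lt(max(abs(st3$log_ratio - 2)), 0.3)
    # BH adjustment equals the sort-based oracle
    for (k in 1:20) {
        p <- runif(sample(5:100, 1))
        expect_equal(p.adjust(p, "BH"), bhOracle(p))
    }
    expect_equal(st2$p_adj, bhOracle(st2$p_raw))
})

test_that("fisherEnrichment builds the 2x2 table and exact p", {
    u <- sprintf("g%02d", 1:20)
    # equal proportions inside and outside the set: fold exactly 1
    res <- fisherEnrichment(u[1:10], u[c(1:5, 11:15)], u)
    expect_equal(res$fold, 1)
    expect_identical(c(res$a, res$b, res$c, res$d), c(5L, 5L, 5L, 5L))
    # a = b = c = d = 1: one-sided p = 5/6 by enumeration
    res2 <- fisherEnrichment(c("g1", "g2"), c("g1", "g3"),
                             c("g1", "g2", "g3", "g4"))
    expect_equal(res2$p_value, 5 / 6)
    expect_error(fisherEnrichment(character(0), u[1], u), "empty")
    expect_error(fisherEnrichment("zz", u[1], u), "subset")
    # under-representation direction
    res3 <- fisherEnrichment(u[1:10], u[11:12], u)
    expect_identical(res3$direction, "under")
    expect_lt(res3$fold, 1)
})

test_that("fisherEnrichment equals hypergeometric enumeration, N <= 30", {
    for (N in c(4, 9, 17, 30)) {
        u <- sprintf("x%02d", seq_len(N))
        for (nset in unique(c(1, 2, N %/% 2, N - 1))) {
            for (K in unique(c(0, 1, N %/% 3, N))) {
                for (a in 0:min(nset, K)) {
                    if (nset - a > N - K) next
                    gs <- u[seq_len(nset)]
                    ps <- u[c(seq_len(a),
                              if (K > a) nset + seq_len(K - a))]
                    if (K == 0) next
                    res <- fisherEnrichment(gs, ps, u)
                    expect_equal(res$p_value,
                                 hyperOracle(res$a, res$b, res$c, res$d),
                                 tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("excess direct targets follow the fold-discounting formula", {
    expect_identical(excessDirectTargets(80, 2), 40L)
    expect_identical(excessDirectTargets(100, 1), 0L)
    expect_identical(excessDirectTargets(60, 3), 40L)
    expect_error(excessDirectTargets(10, 0), "positive")
    # conservation identity before rounding: n * (1 - 1/f) + n / f = n
    for (n in c(10, 80, 123)) for (f in c(1.5, 2, 3.7))
        expect_equal(n * (1 - 1 / f) + n / f, n)
})

test_that("enrichment battery tests DE sets against all property sets", {
    set.seed(33)
    n <- 300
    ids <- sprintf("g%03d", seq_len(n))
    p <- c(runif(30, 0, 1e-4), runif(n - 30))
    stats <- data.frame(gene_id = ids,
                        log_ratio = c(rnorm(30, -2, .2), rnorm(n - 30, 0, .2)),
                        p_raw = p, p_adj = p.adjust(p, "BH"))
    cls <- classifyDE(stats)
    catalog <- list(hit = ids[c(1:20, 250:260)], miss = ids[100:140])
    flags <- data.frame(gene_id = ids,
                        has_motif = seq_len(n) %in% c(1:15, 200:230))
    consv <- data.frame(gene_id = ids,
                        count = ifelse(seq_len(n) <= 10, 5L, 0L))
    bat <- enrichmentBattery(cls, catalog, flags, consv,
                             consThresholds = 2)
    expect_true(all(c("set_name", "property_name", "fold", "p_value",
                      "p_adj") %in% names(bat)))
    sig_hit <- bat[bat$set_name == "significant" &
                   bat$property_name == "hit", ]
    sig_miss <- bat[bat$set_name == "significant" &
                    bat$property_name == "miss", ]
    expect_lt(sig_hit$p_value, 0.05)
    expect_gt(sig_miss$p_value, 0.05)
    # promoter motif property over-represented among the planted down set
    down_motif <- bat[bat$set_name == "down" &
                      bat$property_name == "promoter_motif", ]
    expect_gt(down_motif$fold, 1)
    # empty catalog and no flags: empty table
    expect_identical(nrow(enrichmentBattery(cls)), 0L)
})

test_that("candidate direct targets join significance, motif and conservation", {
    n <- 100
    ids <- sprintf("g%03d", seq_len(n))
    p_adj <- rep(0.5, n)
    p_adj[1:20] <- 1e-4
    stats <- data.frame(gene_id = ids,
                        log_ratio = c(rep(-1.5, 10), rep(1.5, 10),
                                      rep(0.1, 80)),
                        p_raw = p_adj / 2, p_adj = p_adj)
    cls <- classifyDE(stats)
    flags <- data.frame(gene_id = ids,
                        has_motif = seq_len(n) %in% c(1:5, 11:14, 30:40))
    consv <- data.frame(gene_id = ids,
                        count = ifelse(seq_len(n) %in% c(1:3, 11:12, 30:35),
                                       4L, 1L))
    cand <- candidateDirectTargets(stats, cls, flags, consv,
                                   essentialSet = c("g001", "g011"),
                                   minConservation = 2)
    # exactly significant & motif & conserved genes
    expect_identical(sort(cand$gene_id), sprintf("g%03d", c(1:3, 11:12)))
    expect_identical(cand$direction[cand$gene_id == "g001"], "repressed")
    expect_identical(cand$direction[cand$gene_id == "g011"], "activated")
    expect_true(cand$essential[cand$gene_id == "g001"])
    expect_false(cand$essential[cand$gene_id == "g002"])
    # sorted by log ratio: repressed first
    expect_true(!is.unsorted(cand$log_ratio))
    # degenerate filters
    cand0 <- candidateDirectTargets(stats, cls, flags, consv,
                                    minConservation = 0)
    expect_identical(sort(cand0$gene_id),
                     sprintf("g%03d", c(1:5, 11:14)))
    emptyStats <- transform(stats, p_adj = 1)
    clsE <- classifyDE(emptyStats)
    expect_identical(nrow(candidateDirectTargets(emptyStats, clsE, flags,
                                                 consv,
                                                 minConservation = 2)), 0L)
})

test_that("planted motif-DE coupling is detected across seeds", {
    detected_p <- logical(100)
    fold_gt1 <- logical(100)
    for (s in seq_len(100)) {
        plan <- syntheticPlan(seed = 2000 + s, nGenes = 2000L,
                              deFraction = 0.1, motifDeCoupling = 4)
        ids <- sprintf("g%04d", 1:2000)
        set.seed(s)
        flags <- runif(2000) < 0.3
        ex <- generateExpressionDataset(plan, ids, flags)
        stats <- simpleDE(ex$matrix, c(rep("wt", 3), rep("mut", 3)),
                          reference = "wt")
        # panel-level significance (0.05) for the detection-power check:
        # the unmoderated 3v3 test has limited per-gene power, so the
        # stricter classification threshold can leave the query set empty
        cls <- classifyDE(stats, alpha = 0.05)
        res <- fisherEnrichment(downGenes(cls), ids[flags], ids,
                                setName = "down",
                                propertyName = "promoter_motif")
        detected_p[s] <- res$p_value < 0.05
        fold_gt1[s] <- res$fold > 1
    }
    expect_gte(mean(fold_gt1), 0.95)
    expect_gte(mean(detected_p), 0.95)
})
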