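## SMRT IPD-ratio methylome calling: two-state mixing calibration,
## per-strand and per-site classification, windowed chromosomal profiles,
## circular local-linear smoothing and the origin-distance gradient test.

#' Adenine coordinates of GANTC motif sites on both strands
#'
#' A GANTC occurrence at 0-based forward start `s` carries its methylatable
#' adenine at `s + 1` on the forward strand, and at forward coordinate
#' `s + 3` (the T paired with the minus-strand adenine) on the reverse
#' strand.  On circular chromosomes positions are taken modulo the length.
#'
#' @param sites integer vector of 0-based motif start positions.
#' @param chromLength chromosome length in bp.
#' @param circular logical; wrap positions on the circle.
#' @return data.frame with columns `site`, `plus_pos`, `minus_pos`.
#' @examples
#' motifAdenines(100, 4000)   # (+,101) and (-,103)
#' @export
motifAdenines <- function(sites, chromLength, circular = TRUE) {
    sites <- as.integer(sites)
    plus <- sites + 1L
    minus <- sites + 3L
    if (circular) {
        plus <- plus %% as.integer(chromLength)
        minus <- minus %% as.integer(chromLength)
    } else if (any(minus >= chromLength))
        stop("motif extends past the end of a linear contig")
    data.frame(site = sites, plus_pos = plus, minus_pos = minus)
}

.checkIpd <- function(ipd) {
    need <- c("contig", "position0", "strand", "ipd_ratio", "coverage")
    miss <- setdiff(need, names(ipd))
    if (length(miss))
        stop("kinetics table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(!is.finite(ipd$ipd_ratio)))
        stop("kinetics table contains non-finite IPD ratios")
    if (any(ipd$ipd_ratio < 0))
        stop("kinetics table contains negative IPD ratios")
    invisible(ipd)
}

#' Calibrate the two-state mixing model from a fully methylated reference
#'
#' Estimates the fully methylated population-average IPD ratio `r_full` as
#' the (optionally trimmed) mean IPD ratio over motif-adenine observations
#' from a constitutively methylated sample, and derives the theoretical
#' hemi-methylated average `(r_full + 1) / 2`.
#'
#' @param referenceObs kinetics data.frame (`contig`, `position0`,
#'   `strand`, `ipd_ratio`, `coverage`) restricted to motif adenines of the
#'   fully methylated reference strain.
#' @param minCoverage observations with lower coverage are ignored.
#' @param tau under-methylation threshold to store in the model.
#' @param trim trimming fraction passed to [mean()] (0 = plain mean).
#' @return A [CalibrationModel-class].
#' @export
calibrate <- function(referenceObs, minCoverage = 5, tau = 2.4, trim = 0) {
    .checkIpd(referenceObs)
    keep <- referenceObs$coverage >= minCoverage
    if (!any(keep))
        stop("no reference observations at coverage >= ", minCoverage)
    rf <- mean(referenceObs$ipd_ratio[keep], trim = trim)
    if (rf <= (rf + 1) / 2 || rf <= 1)
        stop(sprintf(
            "reference mean IPD ratio (%.3g) is not above the unmethylated baseline; cannot calibrate",
            rf))
    calibrationModel(rf, tau = tau)
}

#' Methylated population fraction from a mean IPD ratio
#'
#' Inverts the linear mixture `r = f * r_full + (1 - f) * 1`:
#' `f = (r - 1) / (r_full - 1)`, clipped to `[0, 1]`.
#'
#' @param meanRatio population-average IPD ratio(s).
#' @param model a [CalibrationModel-class].
#' @param clip clip the fraction into `[0, 1]` (default); set `FALSE` for
#'   the raw diagnostic value.
#' @return Methylated fraction(s) of the same length as `meanRatio`.
#' @examples
#' m <- calibrationModel(7.68)
#' methylatedFraction(2.4, m)   # about 0.21
#' @export
methylatedFraction <- function(meanRatio, model, clip = TRUE) {
    f <- (meanRatio - model@rUnmeth) / (model@rFull - model@rUnmeth)
    if (clip) f <- pmin(1, pmax(0, f))
    f
}

#' Hemi-methylated population fraction from a mean IPD ratio
#'
#' Inverts the mixture of hemi-methylated and unmethylated chromosomes,
#' `r = h * r_hemi + (1 - h) * 1`, giving `h = (r - 1) / (r_hemi - 1)`,
#' clipped to `[0, 1]`.
#'
#' @inheritParams methylatedFraction
#' @return Hemi-methylated fraction(s).
#' @examples
#' hemiMethylatedFraction(2.4, calibrationModel(7.68))   # about 0.42
#' @export
hemiMethylatedFraction <- function(meanRatio, model, clip = TRUE) {
    h <- (meanRatio - model@rUnmeth) / (model@rHemi - model@rUnmeth)
    if (clip) h <- pmin(1, pmax(0, h))
    h
}

#' Per-strand methylation calls at motif adenines
#'
#' Joins a kinetics table to the motif adenine coordinates and labels each
#' strand adenine `under_methylated` when its mean IPD ratio falls strictly
#' below the threshold `tau`, `methylated` otherwise, and `no_data` when
#' the adenine is absent from the table or its coverage is below
#' `minCoverage`.  Multiple observations at one adenine are combined by a
#' coverage-weighted mean.
#'
#' @param ipd kinetics data.frame (`contig`, `position0`, `strand`,
#'   `ipd_ratio`, `coverage`).
#' @param adenines data.frame from [motifAdenines()].
#' @param model a [CalibrationModel-class].
#' @param minCoverage minimum coverage for a call.
#' @return data.frame with one row per (site, strand): `site`, `strand`,
#'   `adenine_position`, `mean_ratio`, `coverage`, `f_raw` (unclipped
#'   fraction), `f_meth` and `label`.
#' @export
callStrands <- function(ipd, adenines, model, minCoverage = 5) {
    .checkIpd(ipd)
    stopifnot(is(model, "CalibrationModel"))
    key <- paste(ipd$position0, ipd$strand)
    agg <- function(keys) {
        idx <- split(seq_along(key), key)[keys]
        ratio <- vapply(idx, function(i) {
            if (is.null(i)) return(NA_real_)
            sum(ipd$ipd_ratio[i] * ipd$coverage[i]) /
                max(1e-12, sum(ipd$coverage[i]))
        }, numeric(1))
        cov <- vapply(idx, function(i)
            if (is.null(i)) 0 else sum(ipd$coverage[i]), numeric(1))
        list(ratio = unname(ratio), cov = unname(cov))
    }
    long <- rbind(
        data.frame(site = adenines$site, strand = "+",
                   adenine_position = adenines$plus_pos),
        data.frame(site = adenines$site, strand = "-",
                   adenine_position = adenines$minus_pos))
    a <- agg(paste(long$adenine_position, long$strand))
    long$mean_ratio <- a$ratio
    long$coverage <- a$cov
    hasData <- !is.na(long$mean_ratio) & long$coverage >= minCoverage
    long$f_raw <- ifelse(hasData,
                         methylatedFraction(long$mean_ratio, model,
                                            clip = FALSE), NA_real_)
    long$f_meth <- ifelse(hasData, pmin(1, pmax(0, long$f_raw)), NA_real_)
    long$label <- ifelse(!hasData, "no_data",
                         ifelse(long$mean_ratio < model@tau,
                                "under_methylated", "methylated"))
    long[order(long$site, long$strand), , drop = FALSE]
}

#' Combine strand calls into per-site methylation classes
#'
#' A site is `under_methylated` when both strands are under-methylated,
#' `asymmetric` when exactly one is, `full` when both are methylated, and
#' `no_data` when either strand lacks data.
#'
#' @param strandCalls data.frame from [callStrands()].
#' @return A list with `calls` (one row per site: strand ratios, fractions,
#'   labels and the site label) and `tally` (named counts over the four
#'   site classes).
#' @export
callSites <- function(strandCalls) {
    plus <- strandCalls[strandCalls$strand == "+", , drop = FALSE]
    minus <- strandCalls[strandCalls$strand == "-", , drop = FALSE]
    m <- match(plus$site, minus$site)
    minus <- minus[m, , drop = FALSE]
    lab <- function(p, q) {
        if (p == "no_data" || q == "no_data") return("no_data")
        u <- (p == "under_methylated") + (q == "under_methylated")
        c("full", "asymmetric", "under_methylated")[u + 1L]
    }
    siteLabel <- mapply(lab, plus$label, minus$label, USE.NAMES = FALSE)
    fSite <- rowMeans(cbind(plus$f_meth, minus$f_meth))
    calls <- data.frame(site = plus$site,
                        plus_ratio = plus$mean_ratio,
                        minus_ratio = minus$mean_ratio,
                        plus_f = plus$f_meth, minus_f = minus$f_meth,
                        f_site = fSite,
                        plus_label = plus$label, minus_label = minus$label,
                        site_label = siteLabel)
    tally <- vapply(c("full", "asymmetric", "under_methylated", "no_data"),
                    function(l) sum(siteLabel == l), integer(1))
    list(calls = calls, tally = tally)
}

#' Windowed chromosomal methylation profile
#'
#' Averages IPD ratios in non-overlapping tiles (20-kb by default) along
#' the chromosome and rescales each window mean onto the percent-fully-
#' methylated scale of the calibration: the fully methylated reference
#' average maps to 100\% and the theoretical hemi-methylated average
#' `(r_full + 1) / 2` to 0\%.
#'
#' @param ipd kinetics data.frame.
#' @param model a [CalibrationModel-class].
#' @param window tile width in bp.
#' @param chromLength chromosome length in bp; the last tile of a
#'   non-multiple length is short.
#' @return data.frame with one row per tile: `start`, `end`, `midpoint`,
#'   `n_obs`, `mean_ratio`, `percent_full` (NA for empty tiles).
#' @export
windowProfile <- function(ipd, model, window = 20000, chromLength) {
    .checkIpd(ipd)
    stopifnot(window > 0, chromLength >= window)
    starts <- seq(0, chromLength - 1, by = window)
    ends <- pmin(starts + window, chromLength)
    idx <- findInterval(ipd$position0, starts)
    mean_ratio <- rep(NA_real_, length(starts))
    n_obs <- integer(length(starts))
    agg <- tapply(ipd$ipd_ratio, idx, mean)
    cnt <- tapply(ipd$ipd_ratio, idx, length)
    at <- as.integer(names(agg))
    mean_ratio[at] <- as.numeric(agg)
    n_obs[at] <- as.integer(cnt)
    data.frame(start = starts, end = ends,
               midpoint = (starts + ends) / 2, n_obs = n_obs,
               mean_ratio = mean_ratio,
               percent_full = 100 * (mean_ratio - model@rHemi) /
                   (model@rFull - model@rHemi))
}

## Tricube-weighted local linear fit at each probe point.  x are
## coordinates (window midpoints), possibly on a circle of size L.
.localLinear <- function(x, y, span, circular, L) {
    n <- length(x)
    q <- max(4L, min(n, as.integer(ceiling(span * n))))
    vapply(seq_len(n), function(i) {
        d <- abs(x - x[i])
        if (circular) d <- pmin(d, L - d)
        o <- order(d)[seq_len(q)]
        dmax <- max(d[o])
        w <- if (dmax == 0) rep(1, q) else (1 - pmin(1, d[o] / dmax)^3)^3
        w[w <= 0] <- 1e-9
        u <- x[o] - x[i]
        if (circular) {
            u <- ((u + L / 2) %% L) - L / 2
        }
        if (sum(w * u^2) - sum(w * u)^2 / sum(w) < 1e-10)
            return(sum(w * y[o]) / sum(w))
        fit <- stats::lm.wfit(cbind(1, u), y[o], w)
        fit$coefficients[1]
    }, numeric(1))
}

#' Smooth a windowed methylation profile
#'
#' Local regression (tricube-weighted local linear fits, the LOESS family)
#' of the percent-fully-methylated profile on window midpoints.  On
#' circular chromosomes distances and local coordinates wrap around the
#' origin junction, so the smoothed curve is continuous across it.
#'
#' @param profile data.frame from [windowProfile()].
#' @param span fraction of windows in each local neighbourhood.
#' @param circular wrap neighbourhoods around the chromosome.
#' @param chromLength chromosome length; defaults to the profile extent.
#' @param value column to smooth (default `"percent_full"`).
#' @return The profile with an added `smoothed_percent` column (NA for
#'   empty windows).
#' @export
smoothProfile <- function(profile, span = 0.75, circular = TRUE,
                          chromLength = max(profile$end),
                          value = "percent_full") {
    ok <- !is.na(profile[[value]])
    if (sum(ok) < 4L)
        stop("need at least 4 non-empty windows to smooth")
    sm <- .localLinear(profile$midpoint[ok], profile[[value]][ok], span,
                       circular, chromLength)
    profile$smoothed_percent <- NA_real_
    profile$smoothed_percent[ok] <- sm
    profile
}

#' Origin-distance gradient test for site methylated fractions
#'
#' Spearman rank correlation between the circular distance of each motif
#' site to the replication origin and its site-mean methylated fraction,
#' with a permutation p-value.  Under a replication-timing gradient, sites
#' near the origin spend longer hemi-methylated, so the correlation is
#' positive.
#'
#' @param siteCalls `calls` data.frame from [callSites()] (needs `site`
#'   and `f_site`), rows with missing fractions are dropped.
#' @param originPosition origin coordinate (0-based bp).
#' @param chromLength chromosome length in bp.
#' @param nPerm number of permutations.
#' @return list with `rho`, `p_value` (two-sided permutation test on
#'   `|rho|`) and `n`.
#' @export
originGradientStat <- function(siteCalls, originPosition, chromLength,
                               nPerm = 10000) {
    keep <- !is.na(siteCalls$f_site)
    x <- siteCalls$site[keep]
    f <- siteCalls$f_site[keep]
    n <- length(x)
    if (n < 3L) stop("need at least 3 sites with data")
    d <- abs(x - originPosition)
    d <- pmin(d, chromLength - d)
    rd <- rank(d)
    rf <- rank(f)
    rd <- rd - mean(rd)
    rf <- rf - mean(rf)
    den <- sqrt(sum(rd^2) * sum(rf^2))
    if (den == 0) return(list(rho = 0, p_value = 1, n = n))
    rho <- sum(rd * rf) / den
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        rb <- sum(rd * rf[sample.int(n)]) / den
        if (abs(rb) >= abs(rho)) exceed <- exceed + 1L
    }
    list(rho = rho, p_value = (exceed + 1) / (nPerm + 1), n = n)
}
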