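#' Group comparisons for binned voxel data
#'
#' Omnibus test plus pairwise post-hoc comparisons for a value grouped by
#' a factor, matching the conventions used for density-bin and
#' visibility-class comparisons: one-way ANOVA with Tukey HSD,
#' Kruskal-Wallis with Dunn's z-tests under Bonferroni adjustment,
#' two-group Mann-Whitney U, or Welch's t-test.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length.
#' @param test `"anova_tukey"`, `"kruskal_dunn_bonf"`, `"mannwhitney"` or
#'   `"welch"` (the last two require exactly two groups).
#' @return list of class `GroupStats`: `test`, `omnibus`
#'   (statistic, df, p), `pairwise` data.frame (estimate = difference of
#'   group means, direction, raw and adjusted p), `groupMeans`.
#' @export
groupStats <- function(values, groups, test = c("anova_tukey",
                       "kruskal_dunn_bonf", "mannwhitney", "welch")) {
    test <- match.arg(test)
    g <- droplevels(as.factor(groups))
    keep <- !is.na(values) & !is.na(g)
    values <- values[keep]; g <- droplevels(g[keep])
    tabn <- table(g)
    if (length(tabn) < 2 || any(tabn < 2))
        stop("need >= 2 groups with >= 2 observations each")
    if (test %in% c("mannwhitney", "welch") && length(tabn) != 2)
        stop(test, " requires exactly 2 groups")
    gm <- tapply(values, g, mean)
    res <- switch(test,
        anova_tukey = {
            fit <- aov(values ~ g)
            an <- summary(fit)[[1]]
            tk <- TukeyHSD(fit)$g
            pw <- data.frame(
                comparison = rownames(tk),
                estimate = tk[, "diff"],
                p_raw = NA_real_,
                p_adj = tk[, "p adj"],
                row.names = NULL)
            list(omnibus = list(statistic = an[1, "F value"],
                                df = unname(an[, "Df"]),
                                p = an[1, "Pr(>F)"]),
                 pairwise = pw)
        },
        kruskal_dunn_bonf = {
            kw <- kruskal.test(values, g)
            pw <- dunnTest(values, g)
            list(omnibus = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value),
                 pairwise = pw)
        },
        mannwhitney = {
            lv <- levels(g)
            wt <- wilcox.test(values[g == lv[1]], values[g == lv[2]],
                              exact = FALSE, correct = TRUE)
            pw <- data.frame(
                comparison = paste(lv[2], "-", lv[1]),
                estimate = gm[2] - gm[1],
                p_raw = wt$p.value, p_adj = wt$p.value,
                row.names = NULL)
            list(omnibus = list(statistic = unname(wt$statistic),
                                df = NA_real_, p = wt$p.value),
                 pairwise = pw)
        },
        welch = {
            lv <- levels(g)
            tt <- t.test(values[g == lv[1]], values[g == lv[2]],
                         var.equal = FALSE)
            pw <- data.frame(
                comparison = paste(lv[2], "-", lv[1]),
                estimate = gm[2] - gm[1],
                p_raw = tt$p.value, p_adj = tt$p.value,
                row.names = NULL)
            list(omnibus = list(statistic = unname(tt$statistic),
                                df = unname(tt$parameter),
                                p = tt$p.value),
                 pairwise = pw)
        })
    res$pairwise$direction <- ifelse(res$pairwise$estimate > 0,
                                     "increase", ifelse(
                                     res$pairwise$estimate < 0,
                                     "decrease", "none"))
    structure(list(test = test, omnibus = res$omnibus,
                   pairwise = res$pairwise, groupMeans = gm,
                   groupSizes = as.integer(tabn)),
              class = "GroupStats")
}

# Dunn's post-hoc z-tests on the joint ranks with tie correction;
# Bonferroni adjustment across all pairs
dunnTest <- function(values, g) {
    r <- rank(values)
    N <- length(values)
    ties <- table(r)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    lv <- levels(g)
    n <- tapply(r, g, length)
    mr <- tapply(r, g, mean)
    pairs <- utils::combn(lv, 2)
    m <- ncol(pairs)
    out <- data.frame(comparison = character(m), estimate = numeric(m),
                      z = numeric(m), p_raw = numeric(m),
                      p_adj = numeric(m), stringsAsFactors = FALSE)
    for (i in seq_len(m)) {
        a <- pairs[1, i]; b <- pairs[2, i]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[a] + 1 / n[b]))
        z <- (mr[b] - mr[a]) / se
        p <- 2 * pnorm(-abs(z))
        out$comparison[i] <- paste(b, "-", a)
        out$estimate[i] <- unname(mr[b] - mr[a])
        out$z[i] <- unname(z)
        out$p_raw[i] <- unname(p)
    }
    out$p_adj <- pmin(1, out$p_raw * m)   # Bonferroni
    out
}

#' @export
print.GroupStats <- function(x, ...) {
    cat(sprintf("Group comparison (%s): %d groups (n = %s)\n", x$test,
                length(x$groupMeans),
                paste(x$groupSizes, collapse = ", ")))
    cat(sprintf("  omnibus statistic %.4g, p = %.3g\n",
                x$omnibus$statistic, x$omnibus$p))
    print(x$pairwise, digits = 4)
    invisible(x)
}

#' Write a group-statistics report to CSV
#'
#' Serializes the omnibus line followed by the pairwise table.
#'
#' @param stats a `GroupStats` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeStatsReport <- function(stats, path) {
    pw <- stats$pairwise
    pw$kind <- "pairwise"
    om <- data.frame(comparison = "omnibus",
                     estimate = NA_real_,
                     p_raw = stats$omnibus$p, p_adj = stats$omnibus$p,
                     direction = NA_character_, kind = "omnibus")
    for (col in setdiff(names(pw), names(om))) om[[col]] <- NA
    write.csv(rbind(om[names(pw)], pw), path, row.names = FALSE)
    invisible(path)
}
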