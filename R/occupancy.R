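#' Call the occupancy category of each nodule assay
#'
#' Decision rule per record: no control band, the assay `FAILED`; control
#' band but no target band, the nodule contains no *nodX*-carrying strain
#' (`NODX_MINUS`); target band fully cut by the diagnostic enzyme,
#' `TOM_ONLY`; fully uncut, `NON_TOM_ONLY`; both cut and uncut products,
#' `MIXED` (TOM plus another *nodX*-positive strain).
#'
#' @param assays `data.frame` with columns `control_band`, `target_band`
#'   (0/1 or logical) and `digest_pattern` (`"CUT"`, `"UNCUT"`, `"BOTH"`,
#'   or `NA` when no target band).
#' @return factor of calls with levels `FAILED`, `NODX_MINUS`, `TOM_ONLY`,
#'   `NON_TOM_ONLY`, `MIXED`.
#' @examples
#' callNodule(data.frame(control_band = 1, target_band = 1,
#'                       digest_pattern = "CUT"))  # TOM_ONLY
#' @export
callNodule <- function(assays) {
    ctrl <- as.logical(assays$control_band)
    targ <- as.logical(assays$target_band)
    pat <- as.character(assays$digest_pattern)
    if (any(targ & is.na(pat)))
        stop("malformed record: target band present but digest pattern NA")
    if (any(!targ & !is.na(pat)))
        stop("malformed record: digest pattern given without a target band")
    if (any(!is.na(pat) & !pat %in% .DIGEST_LEVELS))
        stop("unknown digest pattern(s): ",
             paste(unique(pat[!is.na(pat) & !pat %in% .DIGEST_LEVELS]),
                   collapse = ", "))
    out <- ifelse(!ctrl, "FAILED",
           ifelse(!targ, "NODX_MINUS",
           ifelse(pat == "CUT", "TOM_ONLY",
           ifelse(pat == "UNCUT", "NON_TOM_ONLY", "MIXED"))))
    factor(out, levels = .CALL_LEVELS)
}

#' Aggregate nodule calls into a per-group occupancy table
#'
#' Percentages are computed over genotyped (non-`FAILED`) nodules and
#' rounded half-up to integers; `FAILED` rows keep their count but carry
#' `NA` percent. Groups with no genotyped nodule are excluded with a
#' warning.
#'
#' @param group character/factor group label per nodule.
#' @param call factor from [callNodule()].
#' @return `data.frame` with columns `group`, `category`, `count`,
#'   `percent`; attribute `totalGenotyped` holds the genome-wide count of
#'   non-`FAILED` nodules.
#' @examples
#' calls <- factor(rep(c("NODX_MINUS", "NON_TOM_ONLY"), c(62, 2)),
#'                 levels = levels(callNodule(data.frame(
#'                     control_band = 1, target_band = 0,
#'                     digest_pattern = NA))))
#' occupancyTable(rep("Rondo_control", 64), calls)
#' @export
occupancyTable <- function(group, call) {
    stopifnot(length(group) == length(call))
    group <- as.character(group)
    out <- list()
    for (g in unique(group)) {
        cg <- call[group == g]
        nOK <- sum(cg != "FAILED")
        if (nOK == 0L) {
            warning("group '", g, "' has no genotyped nodule; excluded")
            next
        }
        counts <- table(cg)
        pct <- ifelse(names(counts) == "FAILED", NA_real_,
                      .roundHalfUp(100 * as.numeric(counts) / nOK))
        out[[g]] <- data.frame(group = g, category = names(counts),
                               count = as.integer(counts), percent = pct,
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "totalGenotyped") <- sum(call != "FAILED")
    res
}

#' Fraction of nodules containing the TOM strain
#'
#' The percentage of genotyped (non-`FAILED`) nodules of a group whose call
#' is `TOM_ONLY` or `MIXED`, rounded half-up to an integer.
#'
#' @param tab occupancy table from [occupancyTable()].
#' @param group group label.
#' @return numeric percentage.
#' @export
tomContainingFraction <- function(tab, group) {
    sub <- tab[tab$group == group, ]
    if (!nrow(sub)) stop("group not in table: ", group)
    nOK <- sum(sub$count[sub$category != "FAILED"])
    nTom <- sum(sub$count[sub$category %in% c("TOM_ONLY", "MIXED")])
    .roundHalfUp(100 * nTom / nOK)
}

#' Stacked-bar plot of per-group occupancy
#'
#' @param tab occupancy table from [occupancyTable()].
#' @return A ggplot object.
#' @export
plotOccupancy <- function(tab) {
    tab <- tab[tab$category != "FAILED", ]
    group <- percent <- category <- NULL  # data columns, for R CMD check
    ggplot2::ggplot(tab, ggplot2::aes(x = group, y = percent,
                                      fill = category)) +
        ggplot2::geom_col(position = "stack", colour = "grey20") +
        ggplot2::scale_fill_brewer(palette = "Set2") +
        ggplot2::labs(x = NULL, y = "% of genotyped nodules",
                      fill = "nodule content") +
        ggplot2::theme_bw()
}

#' Kruskal–Wallis rank test on nodule counts
#'
#' Wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic, its degrees of freedom and the chi-square p-value. When every
#' observation is identical the statistic is 0 and p is 1.
#'
#' @param x list of numeric samples (2 or more groups), or a numeric vector
#'   when `g` is given.
#' @param g optional group factor parallel to `x`.
#' @return list with `H`, `df`, `p`.
#' @examples
#' kruskalWallisTest(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.857
#' @export
kruskalWallisTest <- function(x, g = NULL) {
    if (!is.null(g)) x <- split(as.numeric(x), g)
    stopifnot(is.list(x), length(x) >= 2L, all(lengths(x) >= 1L),
              sum(lengths(x)) >= 3L)
    pooled <- unlist(x, use.names = FALSE)
    if (length(unique(pooled)) == 1L)
        return(list(H = 0, df = length(x) - 1L, p = 1))
    kt <- stats::kruskal.test(x)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Welch's t-test on ln-transformed counts
#'
#' Applies `ln(x + offset)` to both samples and runs Welch's unequal-
#' variance t-test with Welch–Satterthwaite degrees of freedom. The offset
#' defaults to 0; use `offset = 1` when zero counts are present.
#'
#' @param a,b numeric samples, each of size >= 2; all values + offset must
#'   be positive.
#' @param offset added before the log transform.
#' @return list with `t`, `df`, `p`.
#' @export
welchLnTest <- function(a, b, offset = 0) {
    stopifnot(length(a) >= 2L, length(b) >= 2L)
    if (any(a + offset <= 0) || any(b + offset <= 0))
        stop("all values + offset must be positive for the ln transform")
    la <- log(a + offset); lb <- log(b + offset)
    if (stats::var(la) == 0 && stats::var(lb) == 0)
        stop("zero variance in both samples: Welch's t is undefined")
    tt <- stats::t.test(la, lb, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}
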