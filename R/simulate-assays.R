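## largest-remainder allocation of n among proportions p; ties broken by
## declaration order
.largestRemainder <- function(n, p) {
    base <- floor(n * p)
    rem <- n - sum(base)
    if (rem > 0) {
        frac <- n * p - base
        give <- order(-frac, seq_along(p))[seq_len(rem)]
        base[give] <- base[give] + 1
    }
    as.integer(base)
}

## assay fields implied by each occupancy category (inverse of callNodule)
.CATEGORY_FIELDS <- data.frame(
    category = c("FAILED", "NODX_MINUS", "TOM_ONLY", "NON_TOM_ONLY", "MIXED"),
    control_band = c(0L, 1L, 1L, 1L, 1L),
    target_band = c(0L, 0L, 1L, 1L, 1L),
    digest_pattern = c(NA, NA, "CUT", "UNCUT", "BOTH"),
    stringsAsFactors = FALSE)

#' Generate per-nodule genotyping assay tables with known categories
#'
#' Draws, per group, a set of nodule records whose occupancy category
#' follows the requested proportions, and emits the PCR/digest observations
#' (control band, target band, digest pattern) each category implies, so
#' that [callNodule()] recovers the truth exactly. In `"exact"` mode
#' category counts are `n * p` rounded by the largest-remainder method
#' (ties broken by the order in which categories are declared); in
#' `"multinomial"` mode they are a multinomial draw.
#'
#' @param groupSizes named integer vector, nodules per group.
#' @param proportions either one named numeric vector of category
#'   proportions (applied to every group) or a named list of such vectors,
#'   one per group. Categories must be from `FAILED`, `NODX_MINUS`,
#'   `TOM_ONLY`, `NON_TOM_ONLY`, `MIXED`; each vector must sum to 1
#'   (tolerance 1e-9) and be non-negative.
#' @param mode `"exact"` or `"multinomial"`.
#' @param seed integer seed.
#' @return list with `assays` (`data.frame`: `nodule_id`, `group`,
#'   `control_band`, `target_band`, `digest_pattern`) and `truth`
#'   (`data.frame`: `nodule_id`, `category`).
#' @examples
#' sim <- generateNoduleAssays(c(A33_TOM = 100),
#'     c(TOM_ONLY = 0.64, MIXED = 0.32, NON_TOM_ONLY = 0.04))
#' table(sim$truth$category)
#' @export
generateNoduleAssays <- function(groupSizes, proportions,
                                 mode = c("exact", "multinomial"),
                                 seed = 1L) {
    mode <- match.arg(mode)
    set.seed(seed)
    if (!is.list(proportions))
        proportions <- stats::setNames(
            rep(list(proportions), length(groupSizes)), names(groupSizes))
    stopifnot(!is.null(names(groupSizes)),
              all(names(groupSizes) %in% names(proportions)))
    rows <- list(); truthRows <- list()
    for (g in names(groupSizes)) {
        n <- groupSizes[[g]]
        if (n <= 0) stop("group size must be positive: ", g)
        p <- proportions[[g]]
        if (any(p < 0)) stop("negative proportions in group ", g)
        if (abs(sum(p) - 1) > 1e-9)
            stop("proportions must sum to 1 in group ", g)
        if (!all(names(p) %in% .CALL_LEVELS))
            stop("unknown categories: ",
                 paste(setdiff(names(p), .CALL_LEVELS), collapse = ", "))
        counts <- if (mode == "exact") .largestRemainder(n, p)
                  else as.integer(stats::rmultinom(1, n, p))
        cats <- rep(names(p), counts)
        cats <- sample(cats)  # shuffle record order within the group
        fields <- .CATEGORY_FIELDS[match(cats, .CATEGORY_FIELDS$category), ]
        id <- sprintf("%s_%03d", g, seq_len(n))
        rows[[g]] <- data.frame(nodule_id = id, group = g,
                                control_band = fields$control_band,
                                target_band = fields$target_band,
                                digest_pattern = fields$digest_pattern,
                                stringsAsFactors = FALSE)
        truthRows[[g]] <- data.frame(nodule_id = id, category = cats,
                                     stringsAsFactors = FALSE)
    }
    assays <- do.call(rbind, rows); rownames(assays) <- NULL
    truth <- do.call(rbind, truthRows); rownames(truth) <- NULL
    list(assays = assays, truth = truth)
}

#' Write / read an assay table as TSV
#'
#' @param assays `data.frame` in the schema of [generateNoduleAssays()].
#' @param path TSV file.
#' @return `writeAssayTable`: `path` invisibly; `readAssayTable`: the
#'   `data.frame`.
#' @export
writeAssayTable <- function(assays, path) {
    utils::write.table(assays, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeAssayTable
#' @export
readAssayTable <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(digest_pattern = "character"))
}
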