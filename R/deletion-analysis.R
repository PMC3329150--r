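## Single and double in-silico reaction deletions ranked by their effect
## on central-metabolic flux spans.

#' Scan reaction deletions for flux-span reduction
#'
#' For each candidate deletion (single reactions or pairs), the reaction
#' is knocked out (bounds fixed to `[0,0]`, which keeps matrix indices
#' stable; the report labels it as a deletion), FVA is run over the
#' central-metabolism set, and the mean flux span is recorded. Results
#' are ranked by ascending mean span; deletions that make the measured
#' rates unattainable are retained with `feasible = FALSE`.
#'
#' @param network a [MetabolicNetwork-class].
#' @param constraints constraint list (measured chemostat rates).
#' @param centralSet reaction ids over which spans are averaged.
#' @param candidates candidate reaction ids; default: reactions classified
#'   `optional` by baseline FVA under `constraints`.
#' @param order 1 (singles) or 2 (all pairs of `candidates`).
#' @param reportThreshold only deletions lowering the mean span by more
#'   than this (default 1 mmol g-1 AFDW h-1) are flagged in the `report`
#'   column; all scanned deletions are returned.
#' @param pruneFloor for `order = 2`: pairs whose two singles each lower
#'   the mean span by less than this are skipped (set `NULL` to disable);
#'   pruning is reported via `message()`.
#' @return data.frame ranked by mean span, with attributes
#'   `"baselineMeanSpan"` and `"spans"` (per-deletion per-reaction spans).
#' @export
deletionSpanScan <- function(network, constraints, centralSet,
                             candidates = NULL, order = 1,
                             reportThreshold = 1, pruneFloor = 0.5) {
  stopifnot(order %in% c(1, 2))
  if (!length(centralSet)) stop("centralSet must be non-empty")
  bad <- setdiff(centralSet, network@reactions$id)
  if (length(bad)) stop("unknown central reactions: ",
                        paste(bad, collapse = ", "))
  baseFva <- runFva(network, constraints, reactions = centralSet)
  base <- fluxSpanSummary(baseFva)$meanSpan
  if (is.null(candidates)) {
    full <- runFva(network, constraints)
    cls <- classifyUsage(full)
    candidates <- names(cls)[cls == "optional"]
    candidates <- setdiff(candidates,
                          network@reactions$id[network@reactions$is_exchange])
  }
  scanOne <- function(ids) {
    cts <- c(constraints, lapply(ids, function(i)
      list(reaction = i, fixed = 0)))
    ok <- tryCatch({
      fva <- runFva(network, cts, reactions = centralSet)
      list(fva = fva)
    }, error = function(e) NULL)
    if (is.null(ok))
      return(list(feasible = FALSE, meanSpan = NA_real_, spans = NULL))
    sm <- fluxSpanSummary(ok$fva)
    list(feasible = TRUE, meanSpan = sm$meanSpan, spans = sm$spans)
  }
  singles <- lapply(candidates, scanOne)
  names(singles) <- candidates
  results <- list(); spanStore <- list()
  record <- function(label, sc) {
    results[[length(results) + 1L]] <<- data.frame(
      deletion = label, feasible = sc$feasible, mean_span = sc$meanSpan,
      delta = base - sc$meanSpan, stringsAsFactors = FALSE)
    spanStore[[label]] <<- sc$spans
  }
  if (order == 1) {
    for (id in candidates) record(id, singles[[id]])
  } else {
    if (length(candidates) < 2) {
      message("fewer than two candidates; no pairs to scan")
      return(structure(data.frame(deletion = character(),
                                  feasible = logical(),
                                  mean_span = numeric(), delta = numeric(),
                                  report = logical()),
                       baselineMeanSpan = base, spans = list()))
    }
    pruned <- 0L
    effect <- vapply(singles, function(s)
      if (s$feasible) base - s$meanSpan else Inf, numeric(1))
    cmb <- utils::combn(candidates, 2)
    for (k in seq_len(ncol(cmb))) {
      pair <- cmb[, k]
      if (!is.null(pruneFloor) &&
          effect[pair[1]] < pruneFloor && effect[pair[2]] < pruneFloor) {
        pruned <- pruned + 1L
        next
      }
      record(paste(pair, collapse = ","), scanOne(pair))
    }
    if (pruned)
      message("pruned ", pruned, " pair(s) whose singles each lower the ",
              "mean span by < ", pruneFloor)
  }
  out <- do.call(rbind, results)
  out$report <- out$feasible & out$delta > reportThreshold
  out <- out[order(!out$feasible, out$mean_span), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baselineMeanSpan") <- base
  attr(out, "spans") <- spanStore
  out
}

#' Default central-metabolism reaction set of the toy network
#'
#' Calvin-cycle carbon fixation, glycogen turnover and catabolism,
#' cyanophycin synthesis, and the photosynthetic/respiratory electron
#' transport chain.
#'
#' @param network a toy [MetabolicNetwork-class]; only reactions present
#'   are returned.
#' @return character vector of reaction ids.
#' @export
toyCentralSet <- function(network) {
  intersect(c("CBB", "GLYSYN", "GLYHYD", "GLYCAT", "CPHSYN", "PSII",
              "CYTB6F", "PSI", "FNR", "FDPQ", "NDH1", "NDH2", "COX", "QOX",
              "ATPASE"),
            network@reactions$id)
}
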