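# Well/condition aggregation, compound scoring against the DMSO control,
# hit calling and ranking, and the statistical comparisons used in the assay.

#' Quantify every field in a plate manifest
#'
#' Reads each stack referenced by the manifest and runs
#' [computeFieldMetrics()]. Calibration/channel metadata is taken from each
#' stack's sidecar unless overridden.
#'
#' @param manifest data.frame from [loadManifest()].
#' @param params analysis parameters from [fieldParams()].
#' @param channelMap,pixelSizeUm,zStepUm optional overrides passed to
#'   [readStack()].
#' @return data.frame with one row per field: \code{well_id},
#'   \code{field_id}, \code{condition}, \code{n_pillars},
#'   \code{n_fully_wrapped}, \code{n_nuclei}, \code{wi}, \code{wi_valid},
#'   plus a list-column \code{sheath_lengths_um}.
#' @export
quantifyManifest <- function(manifest, params = fieldParams(),
                             channelMap = NULL, pixelSizeUm = NULL,
                             zStepUm = NULL) {
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    st <- readStack(manifest$path[i], channelMap = channelMap,
                    pixelSizeUm = pixelSizeUm, zStepUm = zStepUm)
    fm <- computeFieldMetrics(st, params)
    rows[[i]] <- data.frame(
      well_id = manifest$well_id[i], field_id = manifest$field_id[i],
      condition = manifest$condition[i],
      n_pillars = fm@nPillars, n_fully_wrapped = fm@nFullyWrapped,
      n_nuclei = fm@nNuclei, wi = fm@wi, wi_valid = fm@wiValid)
    rows[[i]]$sheath_lengths_um <- list(fm@sheathLengthsUm)
  }
  do.call(rbind, rows)
}

#' Aggregate per-field metrics to condition summaries
#'
#' Pools per-field wrapping indices across all wells and fields of each
#' condition ("all data were pooled and averaged across all fields of
#' view"). Fields with undefined WI (no nuclei) are excluded with a
#' message. Every metrics row must match a manifest row by
#' (well_id, field_id).
#'
#' @param manifest data.frame from [loadManifest()] (columns well_id,
#'   field_id, condition).
#' @param metrics per-field data.frame as returned by [quantifyManifest()]
#'   — minimally well_id, field_id, wi, wi_valid, optionally the
#'   sheath_lengths_um list-column.
#' @return data.frame with one row per condition: \code{condition},
#'   \code{n_fields}, \code{mean_wi}, \code{sem_wi}, plus list-columns
#'   \code{wi_values} (per-field WIs) and \code{sheath_lengths_um}
#'   (pooled).
#' @export
aggregateFields <- function(manifest, metrics) {
  mk <- paste(manifest$well_id, manifest$field_id, sep = "\r")
  xk <- paste(metrics$well_id, metrics$field_id, sep = "\r")
  if (!all(xk %in% mk))
    stop("metrics rows without a matching manifest (well_id, field_id)")
  metrics$condition <- manifest$condition[match(xk, mk)]
  nBad <- sum(!metrics$wi_valid)
  if (nBad > 0L)
    message(nBad, " field(s) with undefined WI (no nuclei) excluded ",
            "from aggregation")
  metrics <- metrics[metrics$wi_valid, , drop = FALSE]
  conds <- unique(manifest$condition)
  out <- lapply(conds, function(cc) {
    sub <- metrics[metrics$condition == cc, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("condition '", cc, "' has zero valid fields")
    wi <- sub$wi
    sheaths <- if ("sheath_lengths_um" %in% names(sub))
      unlist(sub$sheath_lengths_um) else numeric(0)
    r <- data.frame(condition = cc, n_fields = length(wi),
                    mean_wi = mean(wi),
                    sem_wi = if (length(wi) > 1L)
                      sd(wi) / sqrt(length(wi)) else 0)
    r$wi_values <- list(wi)
    r$sheath_lengths_um <- list(sheaths)
    r
  })
  do.call(rbind, out)
}

.findControl <- function(summaries, controlLabel) {
  i <- which(summaries$condition == controlLabel)
  if (length(i) != 1L)
    stop("control condition '", controlLabel,
         "' missing from the summaries")
  i
}

#' Scale condition means by the vehicle control
#'
#' \code{scaled_wi = mean_wi(compound) / mean_wi(control)}; the control
#' itself scales to 1.
#'
#' @param summaries data.frame from [aggregateFields()].
#' @param controlLabel control condition label (default "DMSO").
#' @return data.frame with \code{compound} and \code{scaled_wi}.
#' @export
scaleByControl <- function(summaries, controlLabel = "DMSO") {
  ci <- .findControl(summaries, controlLabel)
  ctrl <- summaries$mean_wi[ci]
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control mean WI must be positive to scale by it")
  data.frame(compound = summaries$condition,
             scaled_wi = summaries$mean_wi / ctrl)
}

#' Call compound hits against the control
#'
#' A compound is a hit iff its mean WI strictly exceeds the control mean
#' plus two standard deviations of the control's per-field WI values — the
#' per-field distribution is the only replicate structure the assay pools.
#'
#' @inheritParams scaleByControl
#' @param nSd number of control standard deviations (default 2).
#' @return data.frame with \code{compound}, \code{mean_wi},
#'   \code{threshold} and \code{hit}; the control row carries
#'   \code{hit = FALSE}.
#' @export
callHits <- function(summaries, controlLabel = "DMSO", nSd = 2) {
  ci <- .findControl(summaries, controlLabel)
  ctrlVals <- summaries$wi_values[[ci]]
  if (length(ctrlVals) < 2L)
    stop("control needs at least 2 fields for a standard deviation")
  thr <- mean(ctrlVals) + nSd * sd(ctrlVals)
  hit <- summaries$mean_wi > thr
  hit[ci] <- FALSE
  data.frame(compound = summaries$condition,
             mean_wi = summaries$mean_wi,
             threshold = thr, hit = hit)
}

#' Rank compounds by control-scaled wrapping index
#'
#' Descending \code{scaled_wi}; ties broken alphabetically by compound
#' label so the ranking is deterministic.
#'
#' @param results data.frame with \code{compound} and \code{scaled_wi}
#'   (from [scaleByControl()]).
#' @return the same rows ordered by rank, with a \code{rank} column
#'   (1 = highest scaled WI).
#' @export
rankCompounds <- function(results) {
  if (nrow(results) < 1L) stop("no compounds to rank")
  ord <- order(-results$scaled_wi, results$compound)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Computes the U statistic for the first sample (number of (x, y) pairs
#' with x > y, ties counting 1/2). For combined sample sizes up to
#' \code{exactLimit} the two-sided p-value is exact, by full enumeration of
#' all relabelings (ties handled by enumerating the observed values
#' themselves): \eqn{p = P(|U - n_1 n_2 / 2| \ge |U_{obs} - n_1 n_2 / 2|)}.
#' For larger samples the normal approximation with tie correction is used.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exactLimit maximum combined n for the exact enumeration
#'   (default 12).
#' @return list with \code{U}, \code{p}, and \code{method}
#'   ("exact" or "normal").
#' @export
mannWhitney <- function(x, y, exactLimit = 12L) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  uStat <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  U <- uStat(x, y)
  N <- n1 + n2
  if (N <= exactLimit) {
    pool <- c(x, y)
    mu <- n1 * n2 / 2
    obsDev <- abs(U - mu)
    labs <- combn(N, n1)
    devs <- apply(labs, 2L, function(ii)
      abs(uStat(pool[ii], pool[-ii]) - mu))
    tol <- sqrt(.Machine$double.eps)
    p <- mean(devs >= obsDev - tol)
    list(U = U, p = p, method = "exact")
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

#' Kruskal-Wallis test over three or more groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (delegates to \code{stats::kruskal.test}).
#'
#' @param groups list of >= 3 non-empty numeric samples.
#' @return list with \code{H}, \code{p} and \code{df}.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("kruskalWallis needs at least 3 groups")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group must be non-empty")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Classic one-way ANOVA (F and p), followed by all pairwise pooled-variance
#' two-sample t tests with p-values multiplied by the number of pairs
#' C(k, 2) and capped at 1.
#'
#' @param groups named list of numeric samples, >= 2 groups of >= 2 values
#'   each.
#' @return list with \code{F}, \code{p} and \code{pairwise} (data.frame:
#'   group1, group2, p_raw, p_adj).
#' @export
anovaBonferroni <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("anovaBonferroni needs at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1))),
                                  levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  tab <- anova(fit)
  Fv <- tab[["F value"]][1L]
  pv <- tab[["Pr(>F)"]][1L]
  # all groups identical -> zero between- and within-group variance
  if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }
  prs <- combn(names(groups), 2L)
  nPairs <- ncol(prs)
  pw <- lapply(seq_len(nPairs), function(j) {
    a <- groups[[prs[1L, j]]]; b <- groups[[prs[2L, j]]]
    p <- if (sd(c(a, b)) == 0) 1
         else stats::t.test(a, b, var.equal = TRUE)$p.value
    data.frame(group1 = prs[1L, j], group2 = prs[2L, j],
               p_raw = p, p_adj = min(1, p * nPairs))
  })
  list(F = Fv, p = pv, pairwise = do.call(rbind, pw))
}

#' Inner wells of a multiwell plate
#'
#' Well labels (row letter + column number, e.g. "B2") excluding the
#' outermost perimeter ring, which suffers accelerated evaporation. An
#' 8 x 12 plate keeps its inner 60 wells.
#'
#' @param rows,cols plate dimensions (each >= 3).
#' @return character vector of well labels, row-major.
#' @examples
#' length(innerWells(8, 12))   # 60
#' @export
innerWells <- function(rows = 8L, cols = 12L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 3L || cols < 3L)
    stop("plate too small: need at least 3 rows and 3 columns ",
         "to have any inner wells")
  if (rows > 26L) stop("row labels beyond 'Z' are not supported")
  as.vector(t(outer(LETTERS[2:(rows - 1L)], 2:(cols - 1L), paste0)))
}

#' Write condition and compound result tables
#'
#' Writes \code{condition_summary.csv} (condition, n_fields, mean_wi,
#' sem_wi) and \code{compound_results.csv} (compound, scaled_wi, hit, rank)
#' into \code{dir}.
#'
#' @param summaries data.frame from [aggregateFields()].
#' @param dir output directory (created if needed).
#' @param controlLabel control condition label.
#' @return invisibly, the compound results data.frame.
#' @export
writeReport <- function(summaries, dir, controlLabel = "DMSO") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(summaries[, c("condition", "n_fields", "mean_wi", "sem_wi")],
            file.path(dir, "condition_summary.csv"), row.names = FALSE)
  scaled <- scaleByControl(summaries, controlLabel)
  hits <- callHits(summaries, controlLabel)
  res <- merge(scaled, hits[, c("compound", "hit")], by = "compound")
  res <- rankCompounds(res)
  write.csv(res, file.path(dir, "compound_results.csv"), row.names = FALSE)
  invisible(res)
}
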