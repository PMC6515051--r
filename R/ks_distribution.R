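# The redundancy-corrected Ks age distribution.  An n-member family carries
# n(n-1)/2 pairwise Ks values but only n-1 duplication events; node
# weighting down-weights the pairs so each event contributes total weight
# one: family members are clustered (average linkage) on their pairwise Ks,
# every internal node of the tree is one duplication event, each pair is
# assigned to the node joining its two members, and its weight is one over
# the number of pairs assigned to that node.

node_weight_one <- function(pf) {
  fid <- pf$family_id[1]
  ok <- is.finite(pf$ks)
  if (!any(ok)) return(NULL)
  members <- sort(unique(c(pf$id_a, pf$id_b)))
  m <- length(members)
  ia <- match(pf$id_a, members)
  ib <- match(pf$id_b, members)
  if (m == 2L) {
    keep <- which(ok)
    return(data.frame(family_id = fid, id_a = pf$id_a[keep],
                      id_b = pf$id_b[keep], ks = pf$ks[keep],
                      node_id = paste0(fid, "_n1"),
                      weight = 1 / length(keep), stringsAsFactors = FALSE))
  }
  D <- matrix(NA_real_, m, m)
  D[cbind(ia, ib)] <- pf$ks
  D[cbind(ib, ia)] <- pf$ks
  ## pairs without a finite estimate (unretained or saturated) are pushed
  ## beyond the oldest observed event so they cannot distort young nodes
  fill <- max(pf$ks[ok]) * 1.5 + 0.5
  D[!is.finite(D)] <- fill
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  node_of <- matrix(NA_integer_, m, m)
  cl <- vector("list", m - 1L)
  for (s in seq_len(m - 1L)) {
    l <- hc$merge[s, 1]
    r <- hc$merge[s, 2]
    lm <- if (l < 0) -l else cl[[l]]
    rm <- if (r < 0) -r else cl[[r]]
    node_of[as.matrix(expand.grid(lm, rm))] <- s
    node_of[as.matrix(expand.grid(rm, lm))] <- s
    cl[[s]] <- c(lm, rm)
  }
  node <- node_of[cbind(ia, ib)]
  keep <- which(ok)
  node <- node[keep]
  w <- 1 / as.numeric(table(node)[as.character(node)])
  out <- data.frame(family_id = fid, id_a = pf$id_a[keep],
                    id_b = pf$id_b[keep], ks = pf$ks[keep],
                    node_id = sprintf("%s_n%d", fid, node),
                    weight = w, stringsAsFactors = FALSE)
  out[order(out$node_id, out$id_a, out$id_b), , drop = FALSE]
}

#' Node-weight the pairwise Ks values of gene families
#'
#' @param pairs data frame with columns `family_id`, `id_a`, `id_b`, `ks`
#'   (e.g. from [estimate_ks_pairs()]).  Pairs with non-finite `ks`
#'   (saturated estimates) participate in neither clustering distance nor
#'   output.
#' @return data frame of weighted pairs: `family_id`, `id_a`, `id_b`, `ks`,
#'   `node_id`, `weight`.  Weights of the pairs sharing a `node_id` sum to
#'   exactly one; a family's total weight equals its number of represented
#'   duplication nodes (at most `n - 1`).  Families whose pairs are all
#'   saturated are dropped with a message.
#' @export
node_weight <- function(pairs) {
  need <- c("family_id", "id_a", "id_b", "ks")
  stopifnot(all(need %in% names(pairs)))
  if (!nrow(pairs))
    return(data.frame(family_id = character(0), id_a = character(0),
                      id_b = character(0), ks = numeric(0),
                      node_id = character(0), weight = numeric(0)))
  fams <- split(pairs, pairs$family_id)
  out <- lapply(fams, node_weight_one)
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " family(ies) dropped: all pairs saturated")
  res <- do.call(rbind, out)
  if (is.null(res)) res <- pairs[0, c("family_id", "id_a", "id_b", "ks")]
  rownames(res) <- NULL
  res
}

#' Filter weighted Ks pairs to the usable range
#'
#' Retains pairs with `min_ks <= ks <= max_ks` (both endpoints inclusive);
#' weights are left untouched.  The defaults drop very young duplicates
#' (allelic variants, assembly redundancy) and saturated old ones.
#'
#' @param weighted output of [node_weight()].
#' @param min_ks,max_ks inclusive bounds (defaults 0.1 and 5).
#' @return the filtered data frame (possibly empty).
#' @export
filter_ks <- function(weighted, min_ks = 0.1, max_ks = 5) {
  weighted[weighted$ks >= min_ks & weighted$ks <= max_ks, , drop = FALSE]
}

#' Weighted Ks histogram
#'
#' Bins are half-open `[x, x + width)` with the last bin closed; bin mass is
#' the summed node weight, so the total equals the retained weight.
#'
#' @param weighted weighted (and typically filtered) Ks pairs.
#' @param bin_width bin width (default 0.1).
#' @param max_ks upper edge of the histogram (default 5).
#' @return object of class `ks_histogram`: list with `breaks`, `bins` (data
#'   frame `bin_lo`, `bin_hi`, `weight`) and `total_weight`.
#' @export
ks_histogram <- function(weighted, bin_width = 0.1, max_ks = 5) {
  breaks <- seq(0, max_ks, by = bin_width)
  nb <- length(breaks) - 1L
  w <- numeric(nb)
  if (nrow(weighted)) {
    inside <- weighted$ks >= 0 & weighted$ks <= max_ks
    idx <- findInterval(weighted$ks[inside], breaks, rightmost.closed = TRUE)
    agg <- tapply(weighted$weight[inside], idx, sum)
    w[as.integer(names(agg))] <- as.numeric(agg)
  }
  structure(list(breaks = breaks,
                 bins = data.frame(bin_lo = breaks[-length(breaks)],
                                   bin_hi = breaks[-1], weight = w),
                 total_weight = sum(w)),
            class = "ks_histogram")
}

#' @export
print.ks_histogram <- function(x, ...) {
  cat(sprintf("ks_histogram: %d bins of %.2g, total weight %.2f\n",
              nrow(x$bins), diff(x$breaks[1:2]), x$total_weight))
  invisible(x)
}

#' Relative bin frequencies of a Ks histogram
#'
#' @param h a [ks_histogram()].
#' @param min_ks drop bins entirely below this value before normalizing
#'   (default 0.1, the retained range's lower bound).
#' @return numeric vector of relative frequencies summing to 1 (all zeros
#'   if the histogram is empty).
#' @export
ks_rel_freq <- function(h, min_ks = 0.1) {
  stopifnot(inherits(h, "ks_histogram"))
  keep <- h$bins$bin_hi > min_ks
  w <- h$bins$weight[keep]
  if (sum(w) > 0) w / sum(w) else w
}

#' Select one representative duplicate pair per family in the peak window
#'
#' Among each family's pairs with Ks inside `[window[1], window[2]]`, the
#' pair whose Ks is closest to the fitted peak mean is kept (ties go to the
#' smaller Ks); with `rule = "boundary"` the distance is instead measured to
#' the nearest window boundary.  Families without an in-window pair are
#' absent from the output.
#'
#' @param weighted weighted Ks pairs (output of [node_weight()]).
#' @param peak_mean fitted Ks-scale mean of the WGD component.
#' @param window Ks window around the peak (default `c(0.9, 1.5)`).
#' @param rule representative choice: `"peak_mean"` (default) or
#'   `"boundary"`.
#' @return one row per family with an in-window pair.
#' @export
select_peak_duplicates <- function(weighted, peak_mean,
                                   window = c(0.9, 1.5),
                                   rule = c("peak_mean", "boundary")) {
  rule <- match.arg(rule)
  inw <- weighted[weighted$ks >= window[1] & weighted$ks <= window[2], ,
                  drop = FALSE]
  if (!nrow(inw)) return(inw)
  d <- if (rule == "peak_mean") abs(inw$ks - peak_mean)
       else pmin(abs(inw$ks - window[1]), abs(inw$ks - window[2]))
  picks <- lapply(split(seq_len(nrow(inw)), inw$family_id), function(rows) {
    rows[order(d[rows], inw$ks[rows])][1]
  })
  out <- inw[unlist(picks), , drop = FALSE]
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a Ks age distribution with optional mixture overlay
#'
#' Bar heights are summed node weights per bin; when a mixture fit is given,
#' the implied Ks-scale density of each log-normal component (and their sum)
#' is overlaid, scaled to the histogram mass.
#'
#' @param h a [ks_histogram()].
#' @param fit optional [em_fit()]/[select_k()] result.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_ks_distribution <- function(h, fit = NULL, main = "Ks age distribution") {
  stopifnot(inherits(h, "ks_histogram"))
  mids <- (h$bins$bin_lo + h$bins$bin_hi) / 2
  bw <- diff(h$breaks[1:2])
  bp <- graphics::barplot(h$bins$weight, width = bw, space = 0,
                          col = "grey85", border = "grey55",
                          xlab = "Ks", ylab = "weighted number of duplicate pairs",
                          main = main)
  graphics::axis(1, at = seq(0, max(h$breaks), 1) / bw * bw *
                   (max(bp) + bw / 2) / max(h$breaks),
                 labels = seq(0, max(h$breaks), 1))
  if (!is.null(fit)) {
    xs <- seq(max(bw / 2, 0.01), max(h$breaks), length.out = 400)
    dens <- vapply(seq_len(fit$k), function(c)
      fit$proportions[c] * stats::dlnorm(xs, fit$means_log[c],
                                         sqrt(fit$variances_log[c])),
      numeric(length(xs)))
    dens <- if (is.matrix(dens)) dens else matrix(dens, ncol = fit$k)
    scale <- h$total_weight * bw
    xplot <- xs / max(h$breaks) * (max(bp) + bw / 2)
    for (c in seq_len(fit$k))
      graphics::lines(xplot, dens[, c] * scale, col = "steelblue")
    graphics::lines(xplot, rowSums(dens) * scale, col = "firebrick", lwd = 2)
  }
  invisible(NULL)
}
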