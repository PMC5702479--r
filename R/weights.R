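#' Read a ROI-to-network partition table
#'
#' @param file two-column tab-delimited file with header `roi`, `network`.
#' @return tibble with columns `roi`, `network`; every ROI is checked to be
#'   assigned exactly one network.
#' @export
read_partition <- function(file) {
  p <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("roi", "network") %in% names(p)))
  if (anyDuplicated(p$roi)) {
    stop("partition error: ROI assigned to more than one network: ",
         paste(unique(p$roi[duplicated(p$roi)]), collapse = ", "))
  }
  tibble::as_tibble(p[c("roi", "network")])
}

#' Packaged cortical/subcortical partition
#'
#' The shipped partition assigns 13 salience, 12 executive, 12 task-negative
#' cortical ROIs and 10 subcortical ROIs (bilateral central-medial and
#' lateral amygdala, periaqueductal gray, habenula and bed nucleus of the
#' stria terminalis) to their networks.
#'
#' @return partition tibble, see [read_partition()].
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "roi_networks.tsv",
                             package = "iscnet", mustWork = TRUE))
}

.partition_index <- function(partition, network, rois) {
  members <- partition$roi[partition$network == network]
  idx <- which(rois %in% members)
  if (length(idx) == 0) {
    stop("empty network: no ROI of network '", network,
         "' present in the matrix")
  }
  idx
}

# weight from a plain matrix given precomputed index sets (fast path shared
# with the permutation engine)
.weight_core <- function(G, i1, i2, mode, include_diagonal, same) {
  sub <- G[i1, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  if (same && !include_diagonal) diag(sub) <- NA_real_
  denom <- if (same && !include_diagonal) n1 * n2 - n1 else n1 * n2
  v <- sub[!is.na(sub)]
  num <- switch(mode,
                positive = sum(v[v > 0]),
                negative = sum(v[v < 0]),
                all = sum(v))
  num / denom
}

#' Within- or between-network connection weight
#'
#' Implements the network weight `W = (1 / (n1 * n2)) * sum of c_ij` over
#' ROI pairs with i in N1 and j in N2, where `c_ij` are group ISM entries.
#' In `"positive"` (`"negative"`) mode only positive (negative) entries
#' enter the sum -- out-of-sign entries contribute zero while the
#' denominator stays `n1 * n2` -- so the all-mode weight decomposes exactly
#' into the positive- plus negative-mode weights. For a within-network
#' weight (`n1 == n2`) the cross-brain self-correlations `c_ii` are included
#' by default; when excluded, the denominator becomes `n1 * n2 - n1`.
#'
#' @param ism a symmetric group `ism` matrix.
#' @param n1,n2 network names present in `partition`.
#' @param partition partition tibble, see [read_partition()].
#' @param mode `"positive"`, `"negative"` or `"all"`.
#' @param include_diagonal include `c_ii` terms for within-network weights.
#'   Default TRUE. Ignored for between-network weights, which never touch
#'   the diagonal.
#' @param normalize `"size"` (default, Eq.-style `n1 * n2` denominator) or
#'   `"count"` (divide by the number of in-sign entries instead).
#' @return weight scalar; attribute `n_undefined` counts ISM entries that
#'   were undefined and therefore excluded from the numerator.
#' @export
network_weight <- function(ism, n1, n2, partition,
                           mode = c("positive", "negative", "all"),
                           include_diagonal = TRUE,
                           normalize = c("size", "count")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  rois <- rownames(ism)
  i1 <- .partition_index(partition, n1, rois)
  i2 <- .partition_index(partition, n2, rois)
  same <- identical(n1, n2)
  G <- unclass(ism)
  sub <- G[i1, i2, drop = FALSE]
  if (same && !include_diagonal) diag(sub) <- NA_real_
  n_undef <- sum(is.na(G[i1, i2, drop = FALSE])) -
    if (same && !include_diagonal) sum(is.na(diag(G[i1, i2, drop = FALSE]))) else 0L
  v <- sub[!is.na(sub)]
  in_sign <- switch(mode, positive = v > 0, negative = v < 0,
                    all = rep(TRUE, length(v)))
  num <- sum(v[in_sign])
  denom <- if (normalize == "count") {
    max(sum(in_sign), 1L)
  } else if (same && !include_diagonal) {
    length(i1) * length(i2) - length(i1)
  } else {
    length(i1) * length(i2)
  }
  structure(num / denom, n_undefined = as.integer(n_undef))
}

#' Network-weight trajectories over dynamic ISMs
#'
#' Reduces a dynamic ISM sequence to one weight per network pair, condition,
#' slice time and mode.
#'
#' @param isms dynamic ISM set from [ism_dynamic()].
#' @param partition partition tibble.
#' @param pairs optional 2-column matrix/data frame of network pairs
#'   (`n1`, `n2`); default all unordered pairs including within-network.
#' @param modes subset of `c("positive", "negative", "all")`.
#' @param include_diagonal see [network_weight()].
#' @return tibble with columns `n1`, `n2`, `condition`, `t` (seconds),
#'   `mode`, `weight`, `n_samples`.
#' @export
weight_trajectories <- function(isms, partition, pairs = NULL,
                                modes = c("positive", "negative", "all"),
                                include_diagonal = TRUE) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(pairs)) {
    nets <- unique(partition$network)
    pairs <- expand.grid(a = seq_along(nets), b = seq_along(nets))
    pairs <- pairs[pairs$a <= pairs$b, ]
    pairs <- data.frame(n1 = nets[pairs$a], n2 = nets[pairs$b],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs)
    names(pairs) <- c("n1", "n2")
  }
  rows <- list()
  for (cond in names(isms)) {
    for (m in isms[[cond]]) {
      for (k in seq_len(nrow(pairs))) {
        for (mode in modes) {
          w <- network_weight(m, pairs$n1[k], pairs$n2[k], partition,
                              mode = mode,
                              include_diagonal = include_diagonal)
          rows[[length(rows) + 1]] <- tibble::tibble(
            n1 = pairs$n1[k], n2 = pairs$n2[k],
            condition = attr(m, "condition"), t = attr(m, "t"),
            mode = mode, weight = as.numeric(w),
            n_samples = attr(m, "sample_count"))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summed connectivity between one subcortical ROI and a target network
#'
#' The raw sum (not the mean) of sign-restricted group ISM entries between a
#' single ROI and every ROI of the target network. The size-normalized
#' equivalent (the sum divided by the target-network size, i.e. the
#' singleton network weight) is attached as attribute `"normalized"`.
#'
#' @param ism symmetric group `ism` matrix.
#' @param roi ROI name; must not belong to `target_network`.
#' @param target_network network name.
#' @param partition partition tibble.
#' @param mode `"positive"`, `"negative"` or `"all"`.
#' @return scalar sum with attribute `normalized`.
#' @export
subcortical_index <- function(ism, roi, target_network, partition,
                              mode = c("positive", "negative", "all")) {
  mode <- match.arg(mode)
  rois <- rownames(ism)
  if (!roi %in% rois) stop("ROI '", roi, "' not in matrix")
  own <- partition$network[partition$roi == roi]
  if (length(own) && own == target_network) {
    stop("ROI '", roi, "' belongs to the target network")
  }
  i2 <- .partition_index(partition, target_network, rois)
  v <- unclass(ism)[roi, i2]
  v <- v[!is.na(v)]
  keep <- switch(mode, positive = v > 0, negative = v < 0,
                 all = rep(TRUE, length(v)))
  s <- sum(v[keep])
  structure(s, normalized = s / length(i2))
}
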