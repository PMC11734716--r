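#' Construct a synapse table
#'
#' One row per synapse: presynaptic neuron id and type (e.g. the ORN
#' receptor type), postsynaptic neuron id, 3D coordinates, and an optional
#' postsynaptic class annotation (`uPN`, `mPN`, `LN`, `other`).
#'
#' @param df Data frame with columns `pre_id`, `pre_type`, `post_id`, `x`,
#'   `y`, `z` and optionally `post_class`.
#' @return The validated data frame with class `synapse_table`.
#' @export
synapse_table <- function(df) {
  need <- c("pre_id", "pre_type", "post_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("synapse table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(as.character(df$pre_id))) ||
      any(!nzchar(as.character(df$post_id))))
    stop("neuron ids must be non-empty", call. = FALSE)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
    stop("synapse coordinates must be finite", call. = FALSE)
  if (!"post_class" %in% names(df)) df$post_class <- "other"
  if (!inherits(df, "synapse_table"))
    class(df) <- c("synapse_table", class(df))
  df
}

#' Read a synapse table from CSV
#'
#' @param path CSV with columns `pre_id`, `pre_type`, `post_id`, `x`, `y`,
#'   `z` and optionally `post_class`.
#' @return A [synapse_table()].
#' @export
read_synapse_csv <- function(path) {
  synapse_table(utils::read.csv(path))
}

#' Assign synapses to glomeruli by clustering their 3D coordinates
#'
#' Glomeruli are spatial clusters of synapses; labels are found by k-means
#' on the raw coordinates with many seeded restarts, so the assignment is
#' deterministic given `seed` and stable (up to label permutation) under
#' rigid motions of the coordinate frame.
#'
#' @param table A [synapse_table()].
#' @param n_clusters Number of glomeruli expected in the volume.
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts.
#' @return The table with an added integer column `cluster`.
#' @export
assign_glomerulus <- function(table, n_clusters, seed = 20250115L,
                              nstart = 25L) {
  table <- synapse_table(table)
  stopifnot(n_clusters >= 1L)
  coords <- as.matrix(table[, c("x", "y", "z")])
  n_distinct <- nrow(unique(coords))
  if (n_distinct < n_clusters)
    stop("need at least n_clusters distinct coordinates (have ",
         n_distinct, ")", call. = FALSE)
  if (n_clusters == 1L) {
    table$cluster <- 1L
    return(table)
  }
  km <- withr::with_seed(seed,
    stats::kmeans(coords, centers = n_clusters, nstart = nstart,
                  iter.max = 100L))
  table$cluster <- km$cluster
  table
}

#' Allocate presynaptic output synapses onto postsynaptic partners
#'
#' The synapse-allocation procedure for one glomerulus and one presynaptic
#' type: (i) discard pre-to-post connections with fewer than
#' `min_per_connection` synapses from a single presynaptic neuron, (ii) sum
#' surviving synapses per postsynaptic neuron, (iii) discard postsynaptic
#' neurons with fewer than `min_total` total synapses, (iv) normalise to
#' the total synapse number for this presynaptic type, (v) rank partners by
#' descending synapse count (ties broken by post id).
#'
#' @param table A [synapse_table()] restricted to one glomerulus and one
#'   `pre_type`.
#' @param min_per_connection Minimum synapses in a single pre-to-post
#'   connection (default 3).
#' @param min_total Minimum total synapses per retained partner (default
#'   10).
#' @param normalize Denominator of the fractions: `"retained"` (total over
#'   synapses surviving both filters, so retained fractions sum to 1) or
#'   `"prefilter"` (total before any filtering).
#' @return An object of class `partner_allocation`: data frame with columns
#'   `post_id`, `total_synapses`, `fraction`, `rank`, `retained` (one row
#'   per retained partner, ordered by rank). Empty input yields an empty
#'   allocation.
#' @examples
#' tab <- data.frame(
#'   pre_id = c("A", "B", "A", "B", "A"), pre_type = "ORNa",
#'   post_id = c("P1", "P1", "P2", "P2", "P3"),
#'   x = 0, y = 0, z = 0)
#' tab <- tab[rep(1:5, c(12, 2, 5, 6, 4)), ]
#' allocate_partners(synapse_table(tab))
#' @export
allocate_partners <- function(table, min_per_connection = 3L,
                              min_total = 10L,
                              normalize = c("retained", "prefilter")) {
  normalize <- match.arg(normalize)
  empty <- data.frame(post_id = character(), total_synapses = integer(),
                      fraction = numeric(), rank = integer(),
                      retained = logical())
  if (nrow(table) == 0L)
    return(structure(empty, class = c("partner_allocation", "data.frame")))
  table <- synapse_table(table)
  if (length(unique(table$pre_type)) > 1L)
    stop("allocate_partners expects a single pre_type; got ",
         paste(unique(table$pre_type), collapse = ", "), call. = FALSE)
  prefilter_total <- nrow(table)

  per_conn <- stats::aggregate(
    list(n = rep(1L, nrow(table))),
    by = list(pre_id = as.character(table$pre_id),
              post_id = as.character(table$post_id)), FUN = sum)
  per_conn <- per_conn[per_conn$n >= min_per_connection, , drop = FALSE]
  if (nrow(per_conn) == 0L)
    return(structure(empty, class = c("partner_allocation", "data.frame")))

  per_post <- stats::aggregate(list(total_synapses = per_conn$n),
                               by = list(post_id = per_conn$post_id),
                               FUN = sum)
  per_post <- per_post[per_post$total_synapses >= min_total, , drop = FALSE]
  if (nrow(per_post) == 0L)
    return(structure(empty, class = c("partner_allocation", "data.frame")))

  denom <- if (normalize == "retained") sum(per_post$total_synapses)
           else prefilter_total
  per_post$fraction <- per_post$total_synapses / denom
  ord <- order(-per_post$total_synapses, per_post$post_id)
  per_post <- per_post[ord, , drop = FALSE]
  per_post$rank <- seq_len(nrow(per_post))
  per_post$retained <- TRUE
  rownames(per_post) <- NULL
  structure(per_post[, c("post_id", "total_synapses", "fraction", "rank",
                         "retained")],
            class = c("partner_allocation", "data.frame"))
}

#' Synapse-count threshold implied by an observed partner count
#'
#' Anterograde trans-synaptic labeling reports only partners above some
#' synapse-count detection threshold. Given a full allocation and the
#' number of partners a labeling experiment observed, returns the smallest
#' non-negative integer threshold `s` such that the number of partners with
#' more than `s` synapses does not exceed the observed count.
#'
#' @param allocation A [allocate_partners()] result.
#' @param observed_partner_count Non-negative integer.
#' @return Integer threshold `s`; monotone non-increasing in
#'   `observed_partner_count`.
#' @examples
#' alloc <- data.frame(post_id = paste0("P", 1:5),
#'                     total_synapses = c(50, 30, 12, 9, 4),
#'                     fraction = NA, rank = 1:5, retained = TRUE)
#' estimate_report_threshold(alloc, 3)  # 9
#' @export
estimate_report_threshold <- function(allocation, observed_partner_count) {
  stopifnot(is.numeric(observed_partner_count),
            observed_partner_count >= 0)
  totals <- allocation$total_synapses
  if (length(totals) == 0L) return(0L)
  for (s in 0:max(totals)) {
    if (sum(totals > s) <= observed_partner_count) return(as.integer(s))
  }
  as.integer(max(totals))
}

#' Cell-class composition of retained partners
#'
#' Joins an allocation with postsynaptic class annotations and tabulates
#' counts and percentages per class over the retained partners. Partners
#' without an annotation count as class `"other"` (so class percentages are
#' lower bounds with incomplete annotation).
#'
#' @param allocation A [allocate_partners()] result.
#' @param class_map Data frame with columns `post_id`, `post_class`, or a
#'   named character vector `post_id -> class`.
#' @return Data frame with columns `post_class`, `n`, `percent`
#'   (percentages sum to 100 over retained partners); empty allocation
#'   yields an empty composition.
#' @export
class_composition <- function(allocation, class_map = NULL) {
  if (nrow(allocation) == 0L)
    return(data.frame(post_class = character(), n = integer(),
                      percent = numeric()))
  ids <- as.character(allocation$post_id)
  cls <- rep("other", length(ids))
  if (!is.null(class_map)) {
    if (is.data.frame(class_map)) {
      m <- match(ids, as.character(class_map$post_id))
      cls[!is.na(m)] <- as.character(class_map$post_class[m[!is.na(m)]])
    } else {
      hit <- ids %in% names(class_map)
      cls[hit] <- unname(class_map[ids[hit]])
    }
  }
  tab <- as.data.frame(table(post_class = cls), stringsAsFactors = FALSE)
  names(tab)[2L] <- "n"
  tab$percent <- 100 * tab$n / sum(tab$n)
  tab
}

#' Left-right symmetry index of innervation volumes
#'
#' Signed percentage \eqn{100 (V_L - V_R) / (2 (V_L + V_R))}, antisymmetric
#' under swapping hemispheres and bounded in \eqn{[-50, 50]}.
#'
#' @param volume_left,volume_right Non-negative volumes (any common unit);
#'   vectorised.
#' @return Signed percentage.
#' @examples
#' innervation_symmetry(300, 100)  # 25
#' @export
innervation_symmetry <- function(volume_left, volume_right) {
  if (any(volume_left < 0) || any(volume_right < 0))
    stop("volumes must be non-negative", call. = FALSE)
  tot <- volume_left + volume_right
  if (any(tot == 0))
    stop("symmetry undefined when both volumes are zero", call. = FALSE)
  100 * (volume_left - volume_right) / (2 * tot)
}

#' Write a partner allocation to CSV
#'
#' @param allocation A [allocate_partners()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allocation_csv <- function(allocation, path) {
  utils::write.csv(
    allocation[, c("post_id", "total_synapses", "fraction", "rank")],
    path, row.names = FALSE)
  invisible(path)
}
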