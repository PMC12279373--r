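#' Cell-type-labeled synapse table
#'
#' One row per unitary connection: a specific presynaptic cell onto a specific
#' postsynaptic cell, with its synapse count and cell-type/side labels.
#'
#' @param df Data.frame with columns `pre_id`, `pre_type`, `pre_side`,
#'   `post_id`, `post_type`, `post_side`, `count` (positive integers);
#'   optional `transmitter`.
#' @return A `synapse_table` (validated data.frame).
#' @export
synapse_table <- function(df) {
  need <- c("pre_id", "pre_type", "pre_side", "post_id", "post_type",
            "post_side", "count")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (any(!is.finite(df$count)) || any(df$count < 1) ||
        any(df$count != round(df$count))) {
      stop("synapse counts must be positive integers")
    }
    if (any(is.na(df$pre_type)) || any(is.na(df$post_type))) {
      stop("missing type labels")
    }
  }
  class(df) <- c("synapse_table", "data.frame")
  df
}

#' Connection-group presets
#'
#' Group-level thresholds used for pathway summaries: `pfl3` keeps groups with
#' at least 200 synapses and at least 1% of both cell types' totals; `mbon32`
#' uses 70 synapses and 0.4%.
#' @export
CONNECTOME_PRESETS <- list(
  pfl3 = list(group_min_synapses = 200, group_min_fraction = 0.01),
  mbon32 = list(group_min_synapses = 70, group_min_fraction = 0.004)
)

#' Group unitary connections by cell type and apply pathway thresholds
#'
#' Filters applied in order: (1) unitary connections with fewer than
#' `unitary_min` synapses are discarded; (2) the survivors are grouped by
#' (pre type, post type) and synapse counts summed within each group;
#' (3) groups with fewer than `group_min_synapses` synapses, or amounting to
#' less than `group_min_fraction` of either the presynaptic type's total
#' output or the postsynaptic type's total input, are discarded. Type totals
#' are computed on the unitary-filtered table before group filtering, so the
#' fraction rule does not depend on which groups survive. Reported connection
#' weights are per hemisphere: half of each group total (sides are pooled
#' within a group).
#'
#' @param t A `synapse_table`.
#' @param unitary_min Minimum synapses per unitary connection (default 5).
#' @param group_min_synapses Minimum synapses per connection group.
#' @param group_min_fraction Minimum fraction of either type total.
#' @param preset Optional `"pfl3"` or `"mbon32"`, filling the two group
#'   thresholds from [CONNECTOME_PRESETS].
#' @return A data.frame of pathway edges: `pre_type`, `post_type`,
#'   `total_synapses`, `weight_per_hemisphere`, `fraction_of_pre_output`,
#'   `fraction_of_post_input`.
#' @export
group_and_filter <- function(t, unitary_min = 5, group_min_synapses = 200,
                             group_min_fraction = 0.01, preset = NULL) {
  t <- synapse_table(as.data.frame(t))
  if (nrow(t) == 0) stop("empty synapse table")
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(CONNECTOME_PRESETS))
    group_min_synapses <- CONNECTOME_PRESETS[[preset]]$group_min_synapses
    group_min_fraction <- CONNECTOME_PRESETS[[preset]]$group_min_fraction
  }
  u <- t[t$count >= unitary_min, , drop = FALSE]
  if (nrow(u) == 0) {
    return(data.frame(pre_type = character(0), post_type = character(0),
                      total_synapses = numeric(0),
                      weight_per_hemisphere = numeric(0),
                      fraction_of_pre_output = numeric(0),
                      fraction_of_post_input = numeric(0)))
  }
  groups <- stats::aggregate(count ~ pre_type + post_type, data = u, FUN = sum)
  pre_tot <- tapply(u$count, u$pre_type, sum)
  post_tot <- tapply(u$count, u$post_type, sum)
  groups$fraction_of_pre_output <- groups$count / as.numeric(pre_tot[groups$pre_type])
  groups$fraction_of_post_input <- groups$count / as.numeric(post_tot[groups$post_type])
  keep <- groups$count >= group_min_synapses &
    groups$fraction_of_pre_output >= group_min_fraction &
    groups$fraction_of_post_input >= group_min_fraction
  out <- groups[keep, , drop = FALSE]
  data.frame(
    pre_type = out$pre_type, post_type = out$post_type,
    total_synapses = out$count,
    weight_per_hemisphere = out$count / 2,
    fraction_of_pre_output = out$fraction_of_pre_output,
    fraction_of_post_input = out$fraction_of_post_input,
    row.names = NULL
  )
}

#' Two-hop pathways between cell types
#'
#' Enumerates source -> intermediate -> target chains over a filtered edge
#' list and ranks intermediates by the weaker of the two edge weights.
#'
#' @param t A `synapse_table`, or a pathway-edge data.frame as returned by
#'   [group_and_filter()].
#' @param source_type,target_type Cell-type labels.
#' @param ... Passed to [group_and_filter()] when `t` is a synapse table.
#' @return A data.frame ranked by descending bottleneck weight:
#'   `intermediate`, `weight_in`, `weight_out`, `bottleneck`.
#' @export
two_hop_paths <- function(t, source_type, target_type, ...) {
  edges <- if (!is.null(t$weight_per_hemisphere)) t else group_and_filter(t, ...)
  first <- edges[edges$pre_type == source_type, , drop = FALSE]
  second <- edges[edges$post_type == target_type, , drop = FALSE]
  mid <- intersect(first$post_type, second$pre_type)
  mid <- setdiff(mid, c(source_type, target_type))
  if (!length(mid)) {
    return(data.frame(intermediate = character(0), weight_in = numeric(0),
                      weight_out = numeric(0), bottleneck = numeric(0)))
  }
  w_in <- first$weight_per_hemisphere[match(mid, first$post_type)]
  w_out <- second$weight_per_hemisphere[match(mid, second$pre_type)]
  out <- data.frame(intermediate = mid, weight_in = w_in, weight_out = w_out,
                    bottleneck = pmin(w_in, w_out))
  out <- out[order(-out$bottleneck), , drop = FALSE]
  rownames(out) <- NULL
  out
}
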