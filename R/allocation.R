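#' Per-protein molecular investment
#'
#' The molecular investment of a protein is its relative molecular
#' count (mean normalized abundance over a condition's replicates)
#' multiplied by its sequence length, i.e. the share of amino acids the
#' cell commits to that protein.  Investments are renormalized to
#' fractions summing to 100 percent.
#'
#' @param abund Protein x sample matrix of normalized abundances.
#' @param lengths Data.frame (`protein_id`, `length_aa`) or a named
#'   numeric vector of residue counts.
#' @param condition Condition label whose replicates are averaged.
#' @param samples Data.frame mapping `sample` to `condition`.
#' @return A data.frame: `protein_id`, `investment` (abundance x
#'   length), `fraction` (percent of total).  Proteins without a length
#'   are dropped with a warning.
#' @export
compute_investment <- function(abund, lengths, condition, samples) {
  abund <- as.matrix(abund)
  cond_of <- stats::setNames(samples$condition, samples$sample)[colnames(abund)]
  cols <- which(cond_of == condition)
  if (length(cols) == 0L) stop("condition not present: ", condition,
                               call. = FALSE)
  len <- if (is.data.frame(lengths)) {
    stats::setNames(lengths$length_aa, lengths$protein_id)
  } else {
    lengths
  }
  ids <- rownames(abund)
  l <- len[ids]
  if (anyNA(l)) {
    warning(sum(is.na(l)), " protein(s) without a sequence length excluded",
            call. = FALSE)
    keep <- !is.na(l)
    abund <- abund[keep, , drop = FALSE]
    ids <- ids[keep]
    l <- l[keep]
  }
  inv <- rowMeans(abund[, cols, drop = FALSE], na.rm = TRUE) * as.numeric(l)
  data.frame(
    protein_id = ids,
    investment = unname(inv),
    fraction = unname(100 * inv / sum(inv)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate investment fractions by functional category
#'
#' Sums per-protein investment fractions over the category paths of a
#' functional hierarchy, at the requested depth.  Fractions at every
#' level sum to 100 percent, and a parent's fraction equals the sum of
#' its children's.
#'
#' @param investments Output of [compute_investment()].
#' @param hierarchy Data.frame with `protein_id` and category columns
#'   `level1`, `level2`, ... (each protein on exactly one leaf path).
#' @param level Depth to aggregate at (1 = top level).
#' @return A data.frame with the category columns up to `level`, a
#'   `category` path label, and `mass_fraction` (percent).
#' @export
aggregate_by_category <- function(investments, hierarchy, level = 1L) {
  level_cols <- paste0("level", seq_len(level))
  assert_columns(hierarchy, c("protein_id", level_cols), "hierarchy")
  idx <- match(investments$protein_id, hierarchy$protein_id)
  if (anyNA(idx)) {
    stop("protein(s) missing from the category hierarchy: ",
         paste(utils::head(investments$protein_id[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(hierarchy[idx, level_cols, drop = FALSE],
                          sep = " / "))
  agg <- rowsum(investments$fraction, group = key)
  out <- data.frame(category = rownames(agg),
                    mass_fraction = agg[, 1L],
                    stringsAsFactors = FALSE, row.names = NULL)
  parts <- do.call(rbind, strsplit(out$category, " / ", fixed = TRUE))
  colnames(parts) <- level_cols
  cbind(as.data.frame(parts, stringsAsFactors = FALSE), out)
}

#' Percent change of category mass fractions between two conditions
#'
#' @param report_a,report_b Outputs of [aggregate_by_category()] for the
#'   baseline and the comparison condition, over the same category tree.
#' @return A data.frame: `category`, `fraction_a`, `fraction_b`,
#'   `change_pct` (relative, `100 * (b - a) / a`) and `change_points`
#'   (absolute percentage-point difference).
#' @export
category_change <- function(report_a, report_b) {
  m <- merge(report_a[, c("category", "mass_fraction")],
             report_b[, c("category", "mass_fraction")],
             by = "category", all = TRUE, suffixes = c("_a", "_b"))
  m$mass_fraction_a[is.na(m$mass_fraction_a)] <- 0
  m$mass_fraction_b[is.na(m$mass_fraction_b)] <- 0
  data.frame(
    category = m$category,
    fraction_a = m$mass_fraction_a,
    fraction_b = m$mass_fraction_b,
    change_pct = ifelse(m$mass_fraction_a > 0,
                        100 * (m$mass_fraction_b - m$mass_fraction_a) /
                          m$mass_fraction_a, NA_real_),
    change_points = m$mass_fraction_b - m$mass_fraction_a,
    stringsAsFactors = FALSE
  )
}

#' Export nested treemap records
#'
#' Converts per-leaf allocation (and optionally per-leaf changes) into
#' a nested node list suitable for any treemap renderer: each node has a
#' `name`, a `size` (investment fraction; internal nodes sum their
#' children), an optional signed `change_pct`, and `children`.
#'
#' @param report Leaf-level output of [aggregate_by_category()] (with
#'   all level columns).
#' @param changes Optional output of [category_change()] matched by
#'   `category`.
#' @return A list of nested node records (one per top-level category).
#' @export
export_treemap_data <- function(report, changes = NULL) {
  if (nrow(report) == 0L) return(list())
  level_cols <- grep("^level[0-9]+$", names(report), value = TRUE)
  change_of <- if (is.null(changes)) NULL else
    stats::setNames(changes$change_pct, changes$category)
  build <- function(rows, depth, path) {
    if (depth > length(level_cols)) return(NULL)
    labs <- unique(rows[[level_cols[depth]]])
    lapply(labs, function(lab) {
      sub <- rows[rows[[level_cols[depth]]] == lab, , drop = FALSE]
      sub_path <- c(path, lab)
      key <- paste(sub_path, collapse = " / ")
      node <- list(name = lab, size = sum(sub$mass_fraction))
      if (!is.null(change_of) && key %in% names(change_of)) {
        node$change_pct <- unname(change_of[key])
      }
      kids <- build(sub, depth + 1L, sub_path)
      if (!is.null(kids) && length(kids) > 0L) node$children <- kids
      node
    })
  }
  build(report, 1L, character())
}
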