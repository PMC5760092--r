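#' Generate a synthetic genome annotation and operon map
#'
#' Places `n_genes` non-overlapping ORFs on a linear chromosome with at
#' least 300 bp of intergenic space, groups a subset of consecutive
#' same-strand genes into operons of 2-4 members, and records each
#' gene's translation start.  Coordinates are 1-based inclusive (GFF
#' convention).  On the plus strand the translation start is the ORF's
#' left coordinate; on the minus strand it is the right coordinate.
#'
#' Operon members are contiguous, share a strand, and are listed in
#' transcription order (rank 1 = promoter-proximal leader).
#'
#' @param config A [sim_config()].
#' @return A list with components `annotation` (data.frame: `gene_id`,
#'   `start`, `end`, `strand`, `tss`) and `operons` (data.frame:
#'   `operon_id`, `gene_id`, `rank`).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  if (n == 0L) {
    return(list(
      annotation = data.frame(gene_id = character(), start = integer(),
                              end = integer(), strand = character(),
                              tss = integer(), stringsAsFactors = FALSE),
      operons = data.frame(operon_id = character(), gene_id = character(),
                           rank = integer(), stringsAsFactors = FALSE)
    ))
  }
  min_len <- 300L
  max_len <- 900L
  min_gap <- 300L
  if (n * (min_len + min_gap) > config$genome_length) {
    stop(sprintf(
      "genome_length %.0f cannot hold %d ORFs of >= %d bp with >= %d bp spacing",
      config$genome_length, n, min_len, min_gap), call. = FALSE)
  }

  withr::with_seed(stage_seed(config$seed, 11L), {
    # ORF lengths in codon multiples; shrink uniformly if the draw
    # overshoots the chromosome (only possible for tight configs).
    len <- sample(seq(min_len, max_len, by = 3L), n, replace = TRUE)
    budget <- config$genome_length - n * min_gap
    if (sum(len) > budget) {
      scale <- budget / sum(len)
      len <- as.integer(pmax(min_len, ((len * scale) %/% 3) * 3))
      if (sum(len) > budget) {
        stop("infeasible ORF packing for this genome_length", call. = FALSE)
      }
    }
    slack <- floor(config$genome_length - sum(len) - n * min_gap)
    extra <- as.integer(rmultinom(1L, size = slack, prob = rep(1, n)))
    gap <- min_gap + extra
    start <- as.integer(cumsum(gap) + cumsum(c(0L, len[-n])) + 1L)
    end <- as.integer(start + len - 1L)

    # Transcription units: operon blocks of 2-4 genes plus singletons,
    # shuffled along the chromosome.
    op_sizes <- if (config$n_operons > 0L) {
      sample(2:4, config$n_operons, replace = TRUE)
    } else {
      integer()
    }
    if (sum(op_sizes) > n) {
      stop("n_operons too large: operon members exceed n_genes", call. = FALSE)
    }
    n_single <- n - sum(op_sizes)
    unit_sizes <- c(op_sizes, rep(1L, n_single))
    unit_is_operon <- c(rep(TRUE, length(op_sizes)), rep(FALSE, n_single))
    ord <- sample.int(length(unit_sizes))
    unit_sizes <- unit_sizes[ord]
    unit_is_operon <- unit_is_operon[ord]
    unit_strand <- ifelse(
      stats::runif(length(unit_sizes)) < config$fraction_minus_strand,
      "-", "+")

    strand <- rep(unit_strand, times = unit_sizes)
    unit_id <- rep(seq_along(unit_sizes), times = unit_sizes)

    gene_id <- sprintf("gene%04d", seq_len(n))
    tss <- ifelse(strand == "+", start, end)

    annotation <- data.frame(
      gene_id = gene_id, start = start, end = end,
      strand = strand, tss = as.integer(tss),
      stringsAsFactors = FALSE
    )

    op_units <- which(unit_is_operon)
    operons <- do.call(rbind, lapply(seq_along(op_units), function(k) {
      u <- op_units[k]
      idx <- which(unit_id == u)
      # transcription order: genomic order on +, reversed on -
      if (unit_strand[u] == "-") idx <- rev(idx)
      data.frame(
        operon_id = sprintf("operon%03d", k),
        gene_id = gene_id[idx],
        rank = seq_along(idx),
        stringsAsFactors = FALSE
      )
    }))
    if (is.null(operons)) {
      operons <- data.frame(operon_id = character(), gene_id = character(),
                            rank = integer(), stringsAsFactors = FALSE)
    }
    list(annotation = annotation, operons = operons)
  })
}

#' Plant a ground-truth regulon
#'
#' Marks `n_up` genes upregulated and `n_down` downregulated, with
#' `n_direct` of the upregulated genes flagged as direct sigma-factor
#' targets (promoter-bound).  Direct targets are planted as whole
#' transcription units: when an operon is selected, every member is
#' marked up and direct, and the binding site is later placed at the
#' operon leader's promoter, so that promoter-to-downstream propagation
#' recovers exactly the planted set.  Remaining direct slots are filled
#' with monocistronic genes.
#'
#' @param annotation,operons Output of [generate_genome()].
#' @param n_up,n_down,n_direct Planted marginal counts; `n_direct <=
#'   n_up` and `n_up + n_down <= n_genes`.
#' @param config A [sim_config()]; supplies effect sizes and the seed.
#' @return A data.frame (`gene_id`, `direction`, `direct`,
#'   `planted_fold`) in annotation order.  `planted_fold` is 1 exactly
#'   for unaffected genes.
#' @export
plant_regulon <- function(annotation, operons, n_up = 300L, n_down = 80L,
                          n_direct = 180L, config = sim_config()) {
  validate_sim_config(config)
  n <- nrow(annotation)
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  n_direct <- as.integer(n_direct)
  if (n_direct > n_up || n_up + n_down > n) {
    stop("infeasible regulon counts: need n_direct <= n_up and n_up + n_down <= n_genes",
         call. = FALSE)
  }
  withr::with_seed(stage_seed(config$seed, 22L), {
    op_split <- split(operons$gene_id[order(operons$rank)],
                      operons$operon_id[order(operons$rank)])
    in_operon <- annotation$gene_id %in% operons$gene_id
    singles <- annotation$gene_id[!in_operon]

    direct <- character()
    if (n_direct > 0L) {
      ops <- sample(op_split)
      for (members in ops) {
        if (length(direct) + length(members) <= n_direct) {
          direct <- c(direct, members)
        }
        if (length(direct) == n_direct) break
      }
      need <- n_direct - length(direct)
      if (need > length(singles)) {
        stop("cannot place n_direct targets: not enough monocistronic genes",
             call. = FALSE)
      }
      if (need > 0L) {
        direct <- c(direct, sample(singles, need))
      }
    }
    # Extra (indirect) up genes come from genes outside the selected
    # operons; down genes from what is left after that.
    selected_ops <- names(op_split)[vapply(op_split, function(m)
      any(m %in% direct), logical(1))]
    blocked <- operons$gene_id[operons$operon_id %in% selected_ops]
    pool_up <- setdiff(annotation$gene_id, union(direct, blocked))
    n_extra <- n_up - n_direct
    if (n_extra > length(pool_up)) {
      stop("infeasible counts: not enough genes left for indirect up calls",
           call. = FALSE)
    }
    extra_up <- if (n_extra > 0L) sample(pool_up, n_extra) else character()
    up <- c(direct, extra_up)
    pool_down <- setdiff(pool_up, extra_up)
    if (n_down > length(pool_down)) {
      stop("infeasible counts: not enough genes left for down calls",
           call. = FALSE)
    }
    down <- if (n_down > 0L) sample(pool_down, n_down) else character()

    direction <- rep("none", n)
    names(direction) <- annotation$gene_id
    direction[up] <- "up"
    direction[down] <- "down"
    planted_fold <- ifelse(direction == "up", config$effect_up,
                           ifelse(direction == "down", config$effect_down, 1))
    data.frame(
      gene_id = annotation$gene_id,
      direction = unname(direction),
      direct = annotation$gene_id %in% direct,
      planted_fold = unname(planted_fold),
      stringsAsFactors = FALSE
    )
  })
}
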