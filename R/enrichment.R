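# Mapping mutation sets onto pathway residues and random-overlap
# expectations.

#' Map a mutation list onto pathway residues via an alignment table
#'
#' Each mutation (a position in a source protein, e.g. a eukaryotic
#' homolog) is mapped through a two-column alignment table onto a residue
#' of the analysed structure, then annotated as lying on a supplied set of
#' pathway residues, immediately sequence-adjacent to one (|delta resno| =
#' 1 on the same chain), or off-pathway.  Positions absent from the table
#' are flagged unmapped.  Duplicate mutations at one position collapse to
#' a single row with a count.
#'
#' @param mutations data frame with columns \code{position} (numeric) and
#'   optionally \code{source}/\code{annotation}, or path to a TSV with a
#'   header row.
#' @param alignment data frame with columns \code{source_position} and
#'   \code{target_resno} (optionally \code{target_chain}), or TSV path.
#' @param pathway_residues integer vector of target residue numbers on the
#'   pathway(s), or labels \code{"chain:resno"}.
#' @param target_chain chain of the pathway residues when given as bare
#'   numbers and the alignment has no chain column.
#' @return Object of class \code{mutation_set}: data frame with source
#'   position, mapped target (\code{"chain:resno"} or \code{"unmapped"}),
#'   \code{count}, and logical \code{on_pathway} / \code{adjacent}.
#' @export
map_mutations <- function(mutations, alignment, pathway_residues,
                          target_chain = "A") {
  read_tsv_checked <- function(x, need) {
    if (is.character(x) && length(x) == 1L) {
      lines <- readLines(x)
      df <- tryCatch(
        utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE),
        error = function(e) stop("malformed table ", x, ": ", conditionMessage(e)))
      x <- df
    }
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("table lacks required column(s): ", paste(miss, collapse = ", "))
    for (cl in need) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(x[[cl]]))))
      if (length(bad))
        stop("malformed value in column '", cl, "' at line ", bad[1] + 1L)
      x[[cl]] <- as.numeric(x[[cl]])
    }
    x
  }
  mutations <- read_tsv_checked(mutations, "position")
  alignment <- read_tsv_checked(alignment, c("source_position", "target_resno"))
  if (!"target_chain" %in% names(alignment))
    alignment$target_chain <- target_chain

  hit <- match(mutations$position, alignment$source_position)
  t_res <- alignment$target_resno[hit]
  t_chn <- alignment$target_chain[hit]
  mapped <- ifelse(is.na(hit), "unmapped", paste0(t_chn, ":", t_res))

  if (is.numeric(pathway_residues))
    pathway_residues <- paste0(target_chain, ":", pathway_residues)
  pw <- strsplit(pathway_residues, ":", fixed = TRUE)
  pw_ch <- vapply(pw, `[[`, "", 1L)
  pw_no <- as.numeric(vapply(pw, `[[`, "", 2L))

  on_pw <- !is.na(hit) & mapped %in% pathway_residues
  adj <- rep(FALSE, length(mapped))
  ok <- which(!is.na(hit) & !on_pw)
  for (k in ok)
    adj[k] <- any(pw_ch == t_chn[k] & abs(pw_no - t_res[k]) == 1)

  out <- data.frame(position = mutations$position, mapped = mapped,
                    on_pathway = on_pw, adjacent = adj,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(out))),
                          by = out[c("position", "mapped", "on_pathway",
                                     "adjacent")], FUN = sum)
  agg <- agg[order(agg$position), c("position", "mapped", "count",
                                    "on_pathway", "adjacent")]
  rownames(agg) <- NULL
  class(agg) <- c("mutation_set", "data.frame")
  agg
}

#' Expected random overlap between a mutation set and pathway residues
#'
#' Under a uniform random placement of \code{n_mutations} distinct
#' positions among \code{n_total_residues}, the expected number landing on
#' the \code{n_pathway_residues} pathway residues is
#' \eqn{n_{mut} \times n_{path} / n_{total}}.  When an observed overlap is
#' supplied, the upper-tail probability of seeing at least that many hits
#' under the hypergeometric null (drawing without replacement) is also
#' reported -- an extension beyond the bare expectation.
#'
#' @param n_mutations number of mapped mutations.
#' @param n_pathway_residues number of pathway residues.
#' @param n_total_residues total residues in the structure.
#' @param observed optional observed overlap count.
#' @return list with \code{expected}, \code{expected_rounded} and (when
#'   \code{observed} is given) \code{p_upper}.
#' @export
overlap_expectation <- function(n_mutations, n_pathway_residues,
                                n_total_residues, observed = NULL) {
  if (n_pathway_residues > n_total_residues)
    stop("n_pathway_residues cannot exceed n_total_residues")
  if (n_mutations < 0 || n_pathway_residues < 0 || n_total_residues <= 0)
    stop("counts must be nonnegative (and n_total_residues positive)")
  expected <- n_mutations * n_pathway_residues / n_total_residues
  out <- list(expected = expected, expected_rounded = round(expected))
  if (!is.null(observed)) {
    out$observed <- observed
    out$p_upper <- stats::phyper(observed - 1, n_pathway_residues,
                                 n_total_residues - n_pathway_residues,
                                 n_mutations, lower.tail = FALSE)
  }
  out
}
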