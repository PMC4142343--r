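#' Summarize a gene-copy inventory
#'
#' Derives the panel-level bookkeeping statistics from a per-copy
#' inventory: how many copies were detected, how many of those are
#' non-functional (and the percentage), how many progenitor-expected
#' copies were lost, how many detected copies are post-polyploidization
#' duplications (detected but not progenitor-expected), how many of those
#' duplications are functional, and the mean number of functional copies
#' per gene. Identities asserted by construction:
#' functional duplications = duplicated - non-functional duplicated, and
#' lost + detected-and-expected = progenitor-expected total.
#'
#' @param inventory data.frame as from [readCopyInventory()].
#' @param n_genes number of genes the copies belong to (> 0). Note that a
#'   capture can pull in close paralog families beyond the intended panel
#'   (co-captured genes); the divisor is the number of gene families
#'   actually analysed.
#' @param digits decimal places for the percentage (default 0, i.e.
#'   nearest integer) and \code{mean_digits} for the per-gene mean
#'   (default 1).
#' @param mean_digits see \code{digits}.
#' @return one-row data.frame with \code{n_detected},
#'   \code{n_nonfunctional}, \code{pct_nonfunctional}, \code{n_lost},
#'   \code{n_duplicated}, \code{n_functional_duplications},
#'   \code{mean_copies_per_gene}, \code{tetraploid_to_diploid_ratio}.
#' @export
summarizeInventory <- function(inventory, n_genes, digits = 0,
                               mean_digits = 1) {
  if (!is.numeric(n_genes) || n_genes <= 0) stop("n_genes must be > 0")
  det <- inventory$detected != "not_detected"
  fun <- det & !is.na(inventory$functional) & inventory$functional
  nonfun <- det & !is.na(inventory$functional) & !inventory$functional
  dup <- det & !inventory$expected_in_progenitor
  lost <- !det & inventory$expected_in_progenitor
  n_detected <- sum(det)
  n_nonfunctional <- sum(nonfun)
  n_duplicated <- sum(dup)
  n_fdup <- sum(dup & fun)
  stopifnot(n_fdup == n_duplicated - sum(dup & nonfun))
  # the 2:1 tetraploid:diploid comparison needs the (unstated) diploid
  # denominator; reported as NA rather than guessed
  data.frame(
    n_detected = n_detected,
    n_nonfunctional = n_nonfunctional,
    pct_nonfunctional = round(100 * n_nonfunctional / n_detected, digits),
    n_lost = sum(lost),
    n_duplicated = n_duplicated,
    n_functional_duplications = n_fdup,
    mean_copies_per_gene = round(sum(fun) / n_genes, mean_digits),
    tetraploid_to_diploid_ratio = NA_real_
  )
}

#' Gene dosage ratio between an activator and a repressor
#'
#' Integer copy counts of two genes in one genotype, starting from the
#' reference copy number (the sum of \code{ref_copies} over the gene's
#' functional detected copies) and adjusting by the genotype's CNV/PAV
#' calls: a \code{loss} call subtracts one copy, a \code{gain} adds one,
#' an \code{absent} call removes all reference copies at that locus.
#' Returned as the ordered pair (activator, repressor), the dosage balance
#' that tips a downstream switch (e.g. the floral activator CO against the
#' repressor TEM1 acting on FT).
#'
#' @param inventory data.frame as from [readCopyInventory()].
#' @param genotype genotype whose calls are applied.
#' @param activator_gene,repressor_gene gene_ids present in the inventory.
#' @param cnv a [CnvCallSet-class] or its calls as a data.frame; only rows
#'   of \code{genotype} are used, excluded rows are ignored.
#' @return named integer vector \code{c(activator =, repressor =)}.
#' @export
dosageRatio <- function(inventory, genotype, activator_gene, repressor_gene,
                        cnv = NULL) {
  calls <- if (is.null(cnv)) NULL
           else if (is(cnv, "CnvCallSet")) as.data.frame(cnv)
           else as.data.frame(cnv)
  count_gene <- function(gene) {
    rows <- inventory[inventory$gene_id == gene &
                        inventory$detected != "not_detected" &
                        !is.na(inventory$functional) & inventory$functional, ,
                      drop = FALSE]
    if (!nrow(rows)) stop("gene not present in inventory: ", gene)
    total <- sum(rows$ref_copies)
    if (!is.null(calls)) {
      gc <- calls[calls$genotype == genotype & !calls$excluded &
                    calls$copy_id %in% rows$copy_id, , drop = FALSE]
      for (i in seq_len(nrow(gc))) {
        delta <- switch(gc$state[i],
          loss = -1L,
          gain = +1L,
          absent = -rows$ref_copies[match(gc$copy_id[i], rows$copy_id)],
          0L)
        total <- total + delta
      }
    }
    if (total < 0)
      stop("inconsistent calls: copy count below zero for ", gene)
    as.integer(total)
  }
  c(activator = count_gene(activator_gene),
    repressor = count_gene(repressor_gene))
}

#' Map a CNV state to its integer copy-number delta
#'
#' CNV states correspond to integer copy changes of +/-1; fractional
#' coverage multipliers round to the nearest integer state, with exact
#' half-way multipliers flagged.
#'
#' @param state character vector of states (\code{normal}, \code{gain},
#'   \code{loss}, \code{absent}).
#' @return integer vector of deltas (absent gives \code{NA}: the whole
#'   locus is removed, the delta depends on the reference copy count).
#' @export
cnvStateDelta <- function(state) {
  unname(c(normal = 0L, gain = 1L, loss = -1L, absent = NA_integer_)[state])
}
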