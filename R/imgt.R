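# 20 canonical amino acids, plus 'X' for unknown residues (always a mismatch)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X")

# package-level cache for the IMGT position rank table
.abmine <- new.env(parent = emptyenv())

# Build the global total order over IMGT position labels "1".."128" with
# optional insertion letters.  Insertions ascend after the bare position at
# every number except 112, where they descend *before* it, so that the CDR3
# junction reads 111, 111A, ..., 112B, 112A, 112 in sequence order.
.build_imgt_ranks <- function() {
  labels <- character(0)
  for (num in 1:128) {
    if (num == 112L) {
      labels <- c(labels, paste0(num, rev(LETTERS)), as.character(num))
    } else {
      labels <- c(labels, as.character(num), paste0(num, LETTERS))
    }
  }
  ranks <- seq_along(labels)
  names(ranks) <- labels
  ranks
}

.imgt_ranks <- function() {
  if (is.null(.abmine$ranks)) .abmine$ranks <- .build_imgt_ranks()
  .abmine$ranks
}

#' Rank of IMGT position labels under the junction-aware total order
#'
#' Positions compare by number first; within a number, insertion codes sort
#' ascending after the bare position everywhere except at 112, where they
#' sort descending before it (the IMGT CDR3 symmetric-gap convention).
#'
#' @param labels character vector of position labels, e.g. `c("111","111A","112")`.
#' @return integer vector of ranks; larger rank means later in sequence order.
#' @examples
#' imgt_rank(c("111", "111A", "112A", "112")) # strictly increasing
#' @export
imgt_rank <- function(labels) {
  r <- .imgt_ranks()[as.character(labels)]
  if (anyNA(r)) {
    bad <- unique(labels[is.na(r)])
    stop("invalid IMGT position label(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Compare two IMGT position labels
#'
#' @param a,b single position labels.
#' @return -1, 0 or 1 as `a` sorts before, equal to, or after `b`.
#' @export
imgt_compare <- function(a, b) {
  sign(imgt_rank(a) - imgt_rank(b))
}

#' Sort IMGT position labels into sequence order
#' @param labels character vector of position labels.
#' @return `labels` sorted under the IMGT total order.
#' @export
imgt_sort <- function(labels) {
  labels[order(imgt_rank(labels))]
}

# integer part of a position label ("111A" -> 111)
imgt_number <- function(labels) {
  as.integer(sub("[A-Z]$", "", labels))
}

#' IMGT region scheme (CDR and framework bounds)
#'
#' The default bounds are the IMGT standard: CDR1 27-38, CDR2 56-65,
#' CDR3 105-117; frameworks are the complementary ranges within 1-128.
#'
#' @param cdr1,cdr2,cdr3 integer length-2 vectors `c(start, end)`.
#' @return object of class `region_scheme`.
#' @export
region_scheme <- function(cdr1 = c(27L, 38L), cdr2 = c(56L, 65L),
                          cdr3 = c(105L, 117L)) {
  ranges <- list(cdr1 = as.integer(cdr1), cdr2 = as.integer(cdr2),
                 cdr3 = as.integer(cdr3))
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > 128L)
      stop("CDR ranges must be c(start, end) within 1..128")
  }
  if (ranges$cdr1[2] >= ranges$cdr2[1] || ranges$cdr2[2] >= ranges$cdr3[1])
    stop("CDR ranges must be disjoint and ordered")
  scheme <- list(
    cdr1 = ranges$cdr1, cdr2 = ranges$cdr2, cdr3 = ranges$cdr3,
    fw1 = c(1L, ranges$cdr1[1] - 1L),
    fw2 = c(ranges$cdr1[2] + 1L, ranges$cdr2[1] - 1L),
    fw3 = c(ranges$cdr2[2] + 1L, ranges$cdr3[1] - 1L),
    fw4 = c(ranges$cdr3[2] + 1L, 128L)
  )
  class(scheme) <- "region_scheme"
  scheme
}

#' Assign each position number to its region
#' @param numbers integer vector of IMGT position numbers (1-128).
#' @param scheme a [region_scheme()].
#' @return character vector: one of fw1, cdr1, fw2, cdr2, fw3, cdr3, fw4.
#' @export
region_of <- function(numbers, scheme = region_scheme()) {
  out <- character(length(numbers))
  for (nm in c("fw1", "cdr1", "fw2", "cdr2", "fw3", "cdr3", "fw4")) {
    rg <- scheme[[nm]]
    out[numbers >= rg[1] & numbers <= rg[2]] <- nm
  }
  out
}

#' Extract the three CDR loops of a numbered chain
#'
#' Residues whose positions fall inside the scheme's CDR ranges, read in
#' IMGT sequence order; a loop absent from the chain yields `""`.
#'
#' @param chain a [numbered_chain()].
#' @param scheme a [region_scheme()].
#' @return named character vector `c(cdr1=, cdr2=, cdr3=)`.
#' @export
extract_cdrs <- function(chain, scheme = region_scheme()) {
  stopifnot(inherits(chain, "numbered_chain"))
  nums <- imgt_number(chain$positions)
  reg <- region_of(nums, scheme)
  out <- c(cdr1 = "", cdr2 = "", cdr3 = "")
  for (nm in names(out)) {
    sel <- reg == nm
    if (any(sel)) out[[nm]] <- paste(chain$residues[sel], collapse = "")
  }
  out
}

#' IMGT position labels for a CDR3 of a given length
#'
#' Implements the junction fill convention: lengths up to 13 occupy
#' 105..117 minus a symmetric central gap; longer loops insert lettered
#' positions at 111 (ascending) and 112 (descending), the 112 side taking
#' the extra position when the overhang is odd.
#'
#' @param n loop length (>= 1).
#' @return character vector of `n` labels in sequence order.
#' @export
imgt_cdr3_positions <- function(n) {
  stopifnot(n >= 1)
  if (n <= 13L) {
    left <- ceiling(n / 2)
    right <- n - left
    labs <- c(as.character(seq(105L, length.out = left)),
              if (right > 0) as.character(seq(118L - right, 117L)))
  } else {
    extra <- n - 13L
    if (extra > 52L) stop("CDR3 longer than the IMGT insertion capacity")
    n111 <- extra %/% 2L
    n112 <- extra - n111
    labs <- c(as.character(105:111),
              if (n111 > 0) paste0("111", LETTERS[seq_len(n111)]),
              if (n112 > 0) paste0("112", rev(LETTERS[seq_len(n112)])),
              as.character(112:117))
  }
  labs
}
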