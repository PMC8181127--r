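#' Topologically order a pedigree
#'
#' Reorders records so every parent precedes its offspring, the order
#' required by the tabular relationship-matrix recursion. Cycles and
#' references to undeclared parents are rejected.
#'
#' @param ped A `pedigree_table` (columns id, parent1, parent2; `NA` =
#'   unknown parent).
#' @return The reordered `pedigree_table`.
#' @export
order_pedigree <- function(ped) {
  ped <- as_pedigree_table(as.data.frame(ped))
  ids <- ped$id
  refs <- setdiff(stats::na.omit(c(ped$parent1, ped$parent2)), ids)
  if (length(refs))
    stop("integrity error: parent(s) not declared as individuals: ",
         paste(refs, collapse = ", "))
  n <- nrow(ped)
  idx <- seq_len(n)
  pos <- setNames(idx, ids)
  p1 <- ifelse(is.na(ped$parent1), 0L, pos[ped$parent1])
  p2 <- ifelse(is.na(ped$parent2), 0L, pos[ped$parent2])
  # Kahn's algorithm on the parent -> offspring DAG
  indeg <- (p1 > 0L) + (p2 > 0L)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(p1[i], p2[i])) if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    cyc <- ids[setdiff(idx, order_out)]
    stop("pedigree error: cycle involving: ", paste(cyc, collapse = ", "))
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}

#' Additive (numerator) relationship matrix
#'
#' Tabular method: for individual i with parents p and q (in an ordered
#' pedigree), `a_ii = 1 + 0.5 a_pq` and `a_ij = 0.5 (a_jp + a_jq)` for j
#' preceding i; unknown parents are treated as unrelated non-inbred
#' founders. The diagonal is 1 plus the inbreeding coefficient.
#'
#' @param ped A `pedigree_table`; reordered internally if needed.
#' @return Symmetric matrix with row/column names equal to the ids, of class
#'   `relationship_matrix`.
#' @export
build_A <- function(ped) {
  ped <- order_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  pos <- setNames(seq_len(n), ids)
  p1 <- ifelse(is.na(ped$parent1), 0L, pos[ped$parent1])
  p2 <- ifelse(is.na(ped$parent2), 0L, pos[ped$parent2])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    f <- p1[i]; m <- p2[i]
    A[i, i] <- 1 + if (f > 0L && m > 0L) 0.5 * A[f, m] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (f > 0L) A[j, f] else rep(0, i - 1L)) +
                    (if (m > 0L) A[j, m] else rep(0, i - 1L)))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  class(A) <- c("relationship_matrix", "matrix", "array")
  A
}
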