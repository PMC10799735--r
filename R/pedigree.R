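# Pedigree construction and additive (numerator) relatedness.
#
# "Relatedness" throughout is the additive relationship a_ij — the expected
# fraction of the genome shared identical-by-descent, times two for the
# diagonal bookkeeping — under which parent-offspring and full siblings are
# 0.5 and half siblings 0.25. Kinship coefficients (half these values) are
# not used anywhere.

#' Build a pedigree from census parent links
#'
#' Links every individual to their recorded mother and father and returns a
#' topologically sorted pedigree (parents strictly before offspring).
#' Unknown parents are treated as distinct, mutually unrelated founders.
#'
#' @param census A `census` data frame (or any data frame with `person_id`,
#'   `mother_id`, `father_id`).
#' @return An object of class `pedigree`: a list with `id` (ids in
#'   topological order), `mother` and `father` (indices into `id`, `NA` for
#'   founders).
#' @export
build_pedigree <- function(census) {
  id <- census$person_id
  n <- length(id)
  mi <- match(census$mother_id, id)
  fi <- match(census$father_id, id)
  dangling <- which((!is.na(census$mother_id) & is.na(mi)) |
                      (!is.na(census$father_id) & is.na(fi)))
  if (length(dangling) > 0) {
    stop("parent id not found in census for: ",
         paste(utils::head(id[dangling], 5), collapse = ", "))
  }
  # Kahn topological sort over child -> parent dependencies.
  indeg <- integer(n)  # number of unplaced parents
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(stats::na.omit(c(mi[i], fi[i])))) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(id[cyc], 10), collapse = ", "))
  }
  rank <- integer(n)
  rank[order] <- seq_len(n)
  structure(list(
    id = id[order],
    mother = rank[mi][order],
    father = rank[fi][order]
  ), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$mother) & is.na(x$father))
  cat(sprintf("<pedigree> %d individuals, %d founders\n",
              length(x$id), founders))
  invisible(x)
}

#' Additive relationship matrix
#'
#' The tabular recursion over a sorted pedigree: for individual i with
#' parents m and f (rows already computed),
#' `a_ij = (a_jm + a_jf) / 2` for earlier j, and `a_ii = 1 + a_mf / 2`.
#' Founders are mutually unrelated and non-inbred (`a_ii = 1`). Inbreeding
#' inflates the diagonal above 1 and can push off-diagonal values above 0.5.
#'
#' @param pedigree A [build_pedigree()] result.
#' @return Symmetric numeric matrix with person ids as dimnames.
#' @export
relatedness_matrix <- function(pedigree) {
  n <- length(pedigree$id)
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    m <- pedigree$mother[i]
    f <- pedigree$father[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      am <- if (is.na(m)) 0 else A[j, m]
      af <- if (is.na(f)) 0 else A[j, f]
      A[j, i] <- A[i, j] <- (am + af) / 2
    }
    A[i, i] <- 1 + if (is.na(m) || is.na(f)) 0 else A[m, f] / 2
  }
  A
}

#' Close biological kin of an ego
#'
#' Alters whose additive relatedness to the ego is at least `threshold`
#' (inclusive, so inbred relationships above 0.5 qualify). At the default
#' threshold of 0.5 these are one's parents, full siblings and children.
#'
#' @param matrix A [relatedness_matrix()].
#' @param ego A person id present in the matrix.
#' @param threshold Minimum relatedness (default 0.5).
#' @return Named numeric vector of relatedness values, names are alter ids;
#'   the ego itself is excluded.
#' @export
close_biological_kin <- function(matrix, ego, threshold = 0.5) {
  if (!ego %in% rownames(matrix)) stop("ego not in relatedness matrix: ", ego)
  a <- matrix[ego, ]
  a <- a[names(a) != ego]
  a[a >= threshold]
}

#' Full siblings recorded in a census
#'
#' Individuals sharing both recorded parents with the ego. Both parents must
#' be present and identical; one shared and one missing parent counts as a
#' half sibling and is excluded.
#'
#' @param census A `census` data frame.
#' @param ego A person id.
#' @return Character vector of sibling ids.
#' @export
full_siblings <- function(census, ego) {
  i <- match(ego, census$person_id)
  if (is.na(i)) stop("ego not in census: ", ego)
  m <- census$mother_id[i]
  f <- census$father_id[i]
  if (is.na(m) || is.na(f)) return(character(0))
  sib <- !is.na(census$mother_id) & census$mother_id == m &
    !is.na(census$father_id) & census$father_id == f &
    census$person_id != ego
  census$person_id[sib]
}

#' Affinal kin of an ego
#'
#' The current partner (coded relatedness 1), and the partner's parents and
#' full siblings, each coded by their pedigree relatedness to the partner
#' (0.5 in the non-inbred case). Partners' half siblings are excluded.
#'
#' @param census A `census` data frame.
#' @param matrix A [relatedness_matrix()] over the same individuals.
#' @param ego A person id.
#' @return Named numeric vector of coded relatedness, names are alter ids;
#'   empty for unpartnered egos.
#' @export
affinal_kin <- function(census, matrix, ego) {
  i <- match(ego, census$person_id)
  if (is.na(i)) stop("ego not in census: ", ego)
  p <- census$partner_id[i]
  if (is.na(p)) return(stats::setNames(numeric(0), character(0)))
  if (!p %in% census$person_id) {
    stop("partner id of '", ego, "' not found in census: ", p)
  }
  out <- stats::setNames(1, p)
  pi <- match(p, census$person_id)
  parents <- stats::na.omit(c(census$mother_id[pi], census$father_id[pi]))
  sibs <- full_siblings(census, p)
  for (alter in c(parents, sibs)) {
    out[alter] <- matrix[alter, p]
  }
  out
}

#' Export positive relatedness values as an edge list
#'
#' @param matrix A [relatedness_matrix()].
#' @param path Output CSV path (`id_i`, `id_j`, `a_ij` for `a_ij > 0`,
#'   upper triangle only).
#' @return Invisibly, the edge-list data frame.
#' @export
write_relatedness_edges <- function(matrix, path) {
  ut <- which(upper.tri(matrix) & matrix > 0, arr.ind = TRUE)
  edges <- data.frame(
    id_i = rownames(matrix)[ut[, 1]],
    id_j = colnames(matrix)[ut[, 2]],
    a_ij = matrix[ut],
    stringsAsFactors = FALSE
  )
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(edges)
}
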