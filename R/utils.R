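# run code under a local RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

#' Coerce a trait table to the internal tips-x-traits matrix
#'
#' Accepts either a data frame whose first column holds tip names (any
#' remaining columns are numeric traits) or a numeric matrix with tip names as
#' rownames. Checks that the tip set equals the tree's tip set and that no
#' value is missing; rows are returned in the tree's tip order.
#'
#' @param tree A validated `phylo` tree.
#' @param traits Data frame (first column = tip names) or numeric matrix with
#'   rownames.
#' @return Numeric matrix, rows ordered as `tree$tip.label`.
#' @export
pr_trait_matrix <- function(tree, traits) {
  if (is.data.frame(traits)) {
    ids <- as.character(traits[[1L]])
    Y <- as.matrix(traits[, -1L, drop = FALSE])
    rownames(Y) <- ids
  } else if (is.matrix(traits)) {
    Y <- traits
  } else {
    stop("traits must be a data frame or a matrix", call. = FALSE)
  }
  storage.mode(Y) <- "double"
  if (is.null(rownames(Y))) stop("traits must name their tips", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  if (anyNA(Y)) stop("traits contain missing values", call. = FALSE)
  missing <- setdiff(tree$tip.label, rownames(Y))
  extra <- setdiff(rownames(Y), tree$tip.label)
  if (length(missing) || length(extra)) {
    stop("trait tips must match tree tips exactly (missing: ",
         paste(utils::head(missing, 5), collapse = ","), "; extra: ",
         paste(utils::head(extra, 5), collapse = ","), ")", call. = FALSE)
  }
  Y[tree$tip.label, , drop = FALSE]
}

# solve A x = b through a Cholesky factor of a symmetric pd matrix
chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

# log-determinant from a Cholesky factor
chol_logdet <- function(R) 2 * sum(log(diag(R)))
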