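#' RNA secondary structure folding backends
#'
#' A folding backend is a function taking a character vector of sequences and
#' returning a data.frame with columns `structure` (dot-bracket) and `mfe`
#' (kcal/mol). The backend is a pluggable contract so that the precursor
#' criteria logic can be tested with injected structures, independently of any
#' particular folding engine.
#'
#' `fold_backend_viennarna()` shells out to the RNAfold command-line tool
#' (thermodynamic minimum free energy). `fold_backend_nussinov()` is a bundled
#' pure-R maximum-pairing backend with a stacking-weighted energy surrogate;
#' it is not thermodynamic and its "mfe" values are a pairing score on a
#' kcal/mol-like scale, suitable for structure topology only.
#'
#' @return a folding backend function.
#' @export
fold_backend_viennarna <- function() {
  function(seqs) {
    n <- length(seqs)
    if (n == 0) return(data.frame(structure = character(0), mfe = numeric(0)))
    fa <- tempfile(fileext = ".fa")
    on.exit(unlink(fa), add = TRUE)
    writeLines(paste0(">s", seq_len(n), "\n", to_rna(seqs)), fa)
    out <- suppressWarnings(
      system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE)
    )
    st <- attr(out, "status")
    if (!is.null(st) && st != 0) stop("RNAfold failed with status ", st)
    # output: >id / sequence / structure ( mfe ) triples
    struct_lines <- out[seq(3, length(out), by = 3)]
    m <- regmatches(
      struct_lines,
      regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", struct_lines)
    )
    bad <- lengths(m) != 3L
    if (any(bad)) stop("unparseable RNAfold output: ", struct_lines[which(bad)[1]])
    data.frame(
      structure = vapply(m, `[`, character(1), 2L),
      mfe = as.numeric(vapply(m, `[`, character(1), 3L)),
      stringsAsFactors = FALSE
    )
  }
}

#' @rdname fold_backend_viennarna
#' @param min_loop minimal hairpin loop length (unpaired bases enclosed by a
#'   pair), default 3.
#' @export
fold_backend_nussinov <- function(min_loop = 3) {
  force(min_loop)
  function(seqs) {
    res <- lapply(seqs, nussinov_fold, min_loop = min_loop)
    data.frame(
      structure = vapply(res, `[[`, character(1), "structure"),
      mfe = vapply(res, `[[`, numeric(1), "mfe"),
      stringsAsFactors = FALSE
    )
  }
}

# Pair weights: GC 3, AU 2, GU 1 (stacking-weighted surrogate); energy is
# -0.9 * total weight, so a ~10-pair mixed stem clears typical MFE cutoffs
# while unstructured sequences do not.
PAIR_WEIGHT <- local({
  w <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  w["G", "C"] <- w["C", "G"] <- 3
  w["A", "T"] <- w["T", "A"] <- 2
  w["G", "T"] <- w["T", "G"] <- 1
  w
})

nussinov_fold <- function(seq, min_loop = 3) {
  s <- strsplit(to_dna(seq), "")[[1]]
  n <- length(s)
  if (n < min_loop + 2) {
    return(list(structure = strrep(".", n), mfe = 0))
  }
  idx <- match(s, DNA_BASES)
  idx[is.na(idx)] <- 1L  # treat ambiguous bases as A (pairs weakly)
  W <- matrix(0, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    i <- seq_len(n - span)
    j <- i + span
    # unpaired j vs paired (i..k-1)+(k..j with k pairs j)
    best <- W[cbind(i, j - 1)]
    for (k0 in 0:(span - min_loop - 1)) {
      k <- i + k0
      pw <- PAIR_WEIGHT[cbind(idx[k], idx[j])]
      left <- ifelse(k0 == 0, 0, W[cbind(i, pmax(k - 1, 1))])
      inner <- W[cbind(k + 1, j - 1)]
      best <- pmax(best, left + inner + pw)
    }
    W[cbind(i, j)] <- best
  }
  # traceback (iterative)
  struct <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (W[i, j] == W[i, j - 1]) {
      stack[[length(stack) + 1]] <- c(i, j - 1L)
      next
    }
    done <- FALSE
    for (k in i:(j - min_loop - 1)) {
      pw <- PAIR_WEIGHT[idx[k], idx[j]]
      if (pw == 0) next
      left <- if (k > i) W[i, k - 1] else 0
      inner <- if (k + 1 <= j - 1) W[k + 1, j - 1] else 0
      if (W[i, j] == left + inner + pw) {
        struct[k] <- "("; struct[j] <- ")"
        if (k > i) stack[[length(stack) + 1]] <- c(i, k - 1L)
        stack[[length(stack) + 1]] <- c(k + 1L, j - 1L)
        done <- TRUE
        break
      }
    }
    if (!done) stack[[length(stack) + 1]] <- c(i, j - 1L)
  }
  score <- W[1, n]
  list(structure = paste(struct, collapse = ""), mfe = -0.9 * score)
}

#' Default folding backend
#'
#' RNAfold when available on the PATH, otherwise the bundled maximum-pairing
#' backend.
#' @export
fold_backend_default <- function() {
  if (nzchar(Sys.which("RNAfold"))) fold_backend_viennarna() else fold_backend_nussinov()
}

#' Fold RNA sequences
#'
#' @param seqs character vector of sequences (DNA or RNA alphabet).
#' @param backend a folding backend function (see [fold_backend_viennarna()]).
#' @return data.frame with columns `structure` and `mfe`, one row per input.
#' @export
fold_rna <- function(seqs, backend = fold_backend_default()) {
  res <- backend(as.character(seqs))
  stopifnot(nrow(res) == length(seqs))
  bad <- nchar(res$structure) != nchar(seqs)
  if (any(bad)) stop("backend returned structure of wrong length for sequence ", which(bad)[1])
  res
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string (balanced).
#' @return integer vector: `pt[i]` is the partner of position i, or NA.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid structure character: ", ch[i])
    }
  }
  if (length(stack)) stop("unbalanced structure: ", length(stack), " open pairs")
  pt
}
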