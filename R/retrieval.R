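# Binary-code retrieval: codes in {-1,+1}^L are bit-packed into bytes and
# ranked by Hamming distance computed with a 256-entry popcount lookup on the
# packed words. Ranking is fully deterministic: ascending distance, ties
# broken by ascending database index.

POPCOUNT8 <- vapply(0:255, function(v) sum(bitwAnd(bitwShiftR(v, 0:7), 1L)),
                    integer(1))

#' Pack and unpack binary codes
#'
#' Codes in \{-1,+1\} are mapped to bits by `(b+1)/2` and packed 8 per byte
#' (bit 0 = least significant). `unpack_codes` inverts the packing exactly for
#' any code length.
#'
#' @param codes `(N, L)` matrix with entries in \{-1,+1\} (a single vector is
#'   treated as one code).
#' @return `pack_codes`: list with `packed` (`N x ceil(L/8)` integer matrix of
#'   byte values) and `L`; `unpack_codes`: the `(N, L)` \{-1,+1\} matrix.
#' @export
pack_codes <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  L <- ncol(codes)
  bits <- (codes + 1) / 2
  if (!all(bits %in% c(0, 1))) stop("codes must have entries in {-1,+1}")
  nb <- ceiling(L / 8)
  packed <- matrix(0L, nrow(codes), nb)
  for (j in seq_len(nb)) {
    lo <- (j - 1L) * 8L + 1L
    hi <- min(j * 8L, L)
    chunk <- bits[, lo:hi, drop = FALSE]
    packed[, j] <- as.integer(chunk %*% 2^(0:(hi - lo)))
  }
  list(packed = packed, L = L)
}

#' @rdname pack_codes
#' @param packed a list as returned by `pack_codes`.
#' @export
unpack_codes <- function(packed) {
  L <- packed$L
  pm <- packed$packed
  out <- matrix(0, nrow(pm), L)
  for (l in seq_len(L)) {
    j <- (l - 1L) %/% 8L + 1L
    s <- (l - 1L) %% 8L
    out[, l] <- bitwAnd(bitwShiftR(pm[, j], s), 1L)
  }
  out * 2 - 1
}

#' Hamming distance between two binary codes
#'
#' Number of differing bits, computed by popcount over packed bytes.
#'
#' @param a,b codes in \{-1,+1\} of equal length L.
#' @return integer in `[0, L]`.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("codes differ in length: ",
                                   length(a), " vs ", length(b))
  pa <- pack_codes(a)$packed
  pb <- pack_codes(b)$packed
  sum(POPCOUNT8[bitwXor(pa, pb) + 1L])
}

#' Build a retrieval index over database codes
#'
#' @param codes `(N, L)` matrix of database codes in \{-1,+1\}.
#' @param labels length-N integer class ids.
#' @param ids optional length-N source identifiers.
#' @return object of class `dafh_index`.
#' @export
retrieval_index <- function(codes, labels, ids = NULL) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  N <- nrow(codes)
  stopifnot(length(labels) == N)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  stopifnot(length(ids) == N)
  pk <- pack_codes(codes)
  structure(list(packed = pk$packed, L = pk$L, N = N,
                 labels = as.integer(labels), ids = as.character(ids)),
            class = "dafh_index")
}

#' @export
print.dafh_index <- function(x, ...) {
  cat("<dafh_index> N=", x$N, " L=", x$L,
      " classes=", length(unique(x$labels)), "\n", sep = "")
  invisible(x)
}

# vector of Hamming distances from one packed query row to all index rows
hamming_to_all <- function(index, qpacked) {
  d <- integer(index$N)
  for (j in seq_len(ncol(index$packed)))
    d <- d + POPCOUNT8[bitwXor(index$packed[, j], qpacked[j]) + 1L]
  d
}

#' Query a retrieval index
#'
#' Ranks database entries by ascending Hamming distance to the query code;
#' equal distances are broken by ascending database index. `k` is clamped to
#' the index size.
#'
#' @param index a [retrieval_index()].
#' @param code query code in \{-1,+1\}^L.
#' @param k number of results to return (default: full ranking).
#' @param exclude_id optional source id excluded from candidates (self-match
#'   exclusion when query and database sets overlap).
#' @return list with `order` (database indices, best first), `distances`
#'   (aligned Hamming distances), `labels`, `ids`.
#' @export
query_index <- function(index, code, k = index$N, exclude_id = NULL) {
  stopifnot(inherits(index, "dafh_index"), index$N >= 1)
  if (length(code) != index$L)
    stop("query code length ", length(code), " != index code length ", index$L)
  d <- hamming_to_all(index, pack_codes(code)$packed[1L, ])
  cand <- seq_len(index$N)
  if (!is.null(exclude_id)) cand <- cand[index$ids[cand] != exclude_id]
  ord <- cand[order(d[cand], cand, method = "radix")]
  k <- max(1L, min(as.integer(k), length(ord)))
  ord <- ord[seq_len(k)]
  list(order = ord, distances = d[ord],
       labels = index$labels[ord], ids = index$ids[ord])
}

#' Save / load a retrieval index
#'
#' The on-disk form is a packed code file (RDS) plus a JSON header recording
#' L, N and the class vocabulary.
#'
#' @param index a `dafh_index`.
#' @param path output file path.
#' @return `save_index` returns `path` invisibly; `load_index` the restored
#'   index.
#' @export
save_index <- function(index, path) {
  saveRDS(unclass(index), path)
  jsonlite::write_json(list(L = index$L, N = index$N,
                            classes = sort(unique(index$labels))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  structure(readRDS(path), class = "dafh_index")
}
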