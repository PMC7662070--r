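#' Pedigree constructor
#'
#' Records of (id, sire, dam) with the unknown-parent sentinel `NA`
#' (accepted on input as `"0"`, `""` or `NA`). Records are topologically
#' sorted so every parent precedes its offspring; parents that never appear
#' as records are added as founders with a warning.
#'
#' @param id,sire,dam character vectors of equal length.
#' @return a `data.frame` of class `pedigree` with columns id, sire, dam,
#'   ancestors before descendants.
#' @examples
#' pedigree(c("C", "A", "B"), c("A", NA, NA), c("B", NA, NA))
#' @export
pedigree <- function(id, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  id <- as.character(id); sire <- norm(sire); dam <- norm(dam)
  stopifnot(length(id) == length(sire), length(id) == length(dam))
  if (anyDuplicated(id)) stop("duplicate pedigree ids: ",
    paste(unique(id[duplicated(id)]), collapse = ", "))
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    warning("parent id(s) never defined, added as founders: ",
            paste(parents, collapse = ", "))
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  ped <- sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors listing a cycle if one exists
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), order)], collapse = ", "))
  }
  ped[order, , drop = FALSE]
}

#' Read a pedigree from delimited text
#'
#' Three tab-separated columns (id, sire, dam), header optional and detected;
#' unknown parents coded `0` or empty. Out-of-order files are re-sorted.
#'
#' @param path file path.
#' @return a [pedigree].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- identical(tolower(first[1:3]), c("id", "sire", "dam"))
  tab <- utils::read.table(path, header = header, sep = "\t",
                           colClasses = "character", na.strings = c("NA", ""))
  if (ncol(tab) < 3) stop("pedigree file must have three columns (id, sire, dam)")
  pedigree(tab[[1]], tab[[2]], tab[[3]])
}

#' Write a pedigree as tab-separated text
#' @param ped a [pedigree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average numerator relationship matrix from a pedigree
#'
#' Recursive tabular method: founders have diagonal 1 and mutual 0;
#' `a(i,j) = 0.5 (a(j, sire_i) + a(j, dam_i))` for earlier j, and
#' `a(i,i) = 1 + 0.5 a(sire_i, dam_i)`; an unknown parent contributes 0.
#'
#' @param ped a [pedigree] (re-sorted internally if needed).
#' @return a [rel_matrix] of kind `"pedigree_A"` labelled by pedigree ids.
#' @examples
#' ped <- pedigree(c("s", "d", "o1", "o2"), c(NA, NA, "s", "s"),
#'                 c(NA, NA, "d", "d"))
#' as.matrix(build_A(ped))["o1", "o2"]  # full sibs: 0.5
#' @export
build_A <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped[[1]], ped[[2]], ped[[3]])
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  rel_matrix(A, labels = ped$id, kind = "pedigree_A")
}
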