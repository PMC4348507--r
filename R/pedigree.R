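#' Construct a pedigree
#'
#' A `Pedigree` is a directed acyclic parent-child structure over
#' individuals. Every individual has either zero or two recorded parents;
#' a single recorded parent is rejected. Parents must themselves be rows of
#' the pedigree and the parent relation must be acyclic.
#'
#' @param id character vector of unique individual ids.
#' @param father,mother character vectors of parent ids; `NA` (or `"0"` in
#'   files) denotes a missing parent.
#' @param sex integer vector (1 = male, 2 = female, 0/NA = unknown). Sex is
#'   only used to validate parent roles; all computations are autosomal.
#' @param genotyped character vector of ids with framework genotypes.
#' @return An object of class `Pedigree` with elements `id`, `father`,
#'   `mother`, `sex`, `genotyped` and a founders-first topological `order`.
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = NA_integer_, genotyped = character()) {
  id <- as.character(id)
  n <- length(id)
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  sex <- rep_len(as.integer(sex), n)
  father[father %in% c("0", "")] <- NA_character_
  mother[mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent))
    stop("individual(s) with exactly one recorded parent: ",
         paste(id[one_parent], collapse = ", "))
  missing_parent <- setdiff(c(father, mother), c(id, NA_character_))
  if (length(missing_parent))
    stop("parent id(s) not present in pedigree: ",
         paste(missing_parent, collapse = ", "))

  fi <- match(father, id)
  mi <- match(mother, id)
  ord <- topo_order(fi, mi, id)

  ped <- structure(
    list(id = id, father = father, mother = mother, sex = sex,
         genotyped = intersect(id, as.character(genotyped)),
         order = ord, .cache = new.env(parent = emptyenv())),
    class = "Pedigree")
  ped
}

# Kahn topological sort, founders first; stops on a cycle.
topo_order <- function(fi, mi, id) {
  n <- length(id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n)
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), out)], collapse = ", "))
  out
}

#' Load a pedigree from a PED-style text file
#'
#' Reads whitespace-delimited rows `id father mother sex`; `"0"` denotes a
#' missing parent. Row order is irrelevant.
#'
#' @param path path to the pedigree file.
#' @param genotyped optional character vector of genotyped ids.
#' @return A [pedigree()] object.
#' @export
load_pedigree <- function(path, genotyped = character()) {
  tab <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 4) stop("pedigree file needs columns: id father mother sex")
  pedigree(tab[[1]], tab[[2]], tab[[3]], suppressWarnings(as.integer(tab[[4]])),
           genotyped = genotyped)
}

#' @export
print.Pedigree <- function(x, ...) {
  nf <- sum(is.na(x$father))
  cat(sprintf("Pedigree: %d individuals (%d founders, %d genotyped)\n",
              length(x$id), nf, length(x$genotyped)))
  invisible(x)
}

#' Pedigree kinship coefficients
#'
#' `kinship_matrix()` computes the full matrix of kinship coefficients by
#' the standard tabular recursion over a founders-first ordering: distinct
#' founders have kinship 0, self-kinship is (1 + parental kinship)/2, and
#' otherwise the coefficient averages over the parents of the later-born
#' individual. Founders are assumed non-inbred. The matrix is cached on the
#' pedigree, so repeated calls are free.
#'
#' `kinship()` returns the coefficient for one pair.
#'
#' @param ped a [pedigree()] object.
#' @return `kinship_matrix()`: a symmetric numeric matrix with dimnames set
#'   to the individual ids. `kinship()`: a number in \[0, 1\].
#' @export
kinship_matrix <- function(ped) {
  cache <- ped$.cache
  if (!is.null(cache$kin)) return(cache$kin)
  n <- length(ped$id)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ped$order) {
    f <- fi[i]; m <- mi[i]
    if (is.na(f)) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[f, m])
      prev <- ped$order[seq_len(which(ped$order == i) - 1L)]
      if (length(prev)) {
        v <- 0.5 * (K[f, prev] + K[m, prev])
        K[i, prev] <- v
        K[prev, i] <- v
      }
    }
  }
  cache$kin <- K
  K
}

#' @rdname kinship_matrix
#' @param i,j individual ids.
#' @export
kinship <- function(ped, i, j) {
  K <- kinship_matrix(ped)
  i <- as.character(i); j <- as.character(j)
  if (!(i %in% ped$id) || !(j %in% ped$id))
    stop("unknown individual id: ", paste(setdiff(c(i, j), ped$id), collapse = ", "))
  K[i, j]
}

#' Quasi-founders of the genotyped sub-pedigree
#'
#' A quasi-founder is a genotyped individual for whom not both parents are
#' genotyped; quasi-founders form the top of the genotyped sub-pedigree and
#' are the individuals whose haplotypes cannot be labelled paternal or
#' maternal by Mendelian rules alone.
#'
#' @param ped a [pedigree()] object with its `genotyped` set populated.
#' @return Character vector of quasi-founder ids.
#' @export
quasi_founders <- function(ped) {
  g <- ped$genotyped
  idx <- match(g, ped$id)
  both <- ped$father[idx] %in% g & ped$mother[idx] %in% g
  g[!both]
}

#' Nuclear families of a pedigree
#'
#' One family per distinct (father, mother) couple with at least one child.
#'
#' @param ped a [pedigree()] object.
#' @return List of `NuclearFamily` objects, each with `father`, `mother` and
#'   `children` ids.
#' @export
nuclear_families <- function(ped) {
  has_par <- !is.na(ped$father)
  if (!any(has_par)) return(list())
  key <- paste(ped$father[has_par], ped$mother[has_par], sep = "\r")
  fams <- split(ped$id[has_par], key)
  out <- lapply(names(fams), function(k) {
    pm <- strsplit(k, "\r", fixed = TRUE)[[1]]
    structure(list(father = pm[1], mother = pm[2], children = fams[[k]]),
              class = "NuclearFamily")
  })
  ord <- order(vapply(out, function(f) match(f$children[1], ped$id[ped$order]), 1L))
  out[ord]
}

#' @export
print.NuclearFamily <- function(x, ...) {
  cat(sprintf("NuclearFamily: %s x %s, %d child(ren)\n",
              x$father, x$mother, length(x$children)))
  invisible(x)
}

# All descendants of `id` (ids), excluding `id` itself.
descendants <- function(ped, id) {
  out <- character(0)
  frontier <- as.character(id)
  repeat {
    kids <- ped$id[ped$father %in% frontier | ped$mother %in% frontier]
    kids <- setdiff(kids, out)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
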