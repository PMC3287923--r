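#' Construct a Pedigree
#'
#' Builds a validated, topologically sorted pedigree from parallel member
#' vectors. Missing parents may be given as \code{NA}, \code{""} or \code{"0"}
#' (the PLINK FAM convention); both parents must be missing (founder) or both
#' present. Members may be supplied in any order; they are sorted so that
#' parents precede offspring, which also rules out an individual being its own
#' ancestor.
#'
#' @param famID family identifier.
#' @param id,father,mother character vectors of member and parent ids.
#' @param sex \code{"male"}/\code{"female"}, or numeric 1 = male, 2 = female.
#' @return a [Pedigree-class] object.
#' @examples
#' trio <- Pedigree("1", id = c("kid", "dad", "mom"),
#'                  father = c("dad", NA, NA), mother = c("mom", NA, NA),
#'                  sex = c(1, 1, 2))
#' members(trio)$id   # founders first
#' @export
Pedigree <- function(famID, id, father, mother, sex) {
  famID <- as.character(famID)
  id <- as.character(id)
  norm <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & (p == "0" | p == "")] <- NA_character_
    p
  }
  father <- norm(father)
  mother <- norm(mother)
  if (is.numeric(sex)) sex <- c("male", "female")[sex]
  sex <- as.character(sex)
  if (anyDuplicated(id))
    stop(sprintf("duplicate individual id '%s' in family %s",
                 id[duplicated(id)][1L], famID))
  half <- xor(is.na(father), is.na(mother))
  if (any(half))
    stop(sprintf("individual %s in family %s has exactly one missing parent",
                 id[half][1L], famID))
  for (p in setdiff(c(father, mother), c(id, NA)))
    stop(sprintf("individual %s in family %s references parent '%s' not present in the family",
                 id[which(father == p | mother == p)[1L]], famID, p))
  ord <- topoOrder(id, father, mother, famID)
  m <- data.frame(id = id, father = father, mother = mother, sex = sex,
                  stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(m) <- NULL
  m$founder <- is.na(m$father)
  new("Pedigree", famID = famID, members = m)
}

# Kahn's algorithm; errors on cycles naming the individuals involved.
topoOrder <- function(id, father, mother, famID) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  indeg <- as.integer(!is.na(father)) + as.integer(!is.na(mother))
  kids <- vector("list", n)
  for (i in idx[!is.na(father)]) {
    fi <- idx[[father[i]]]; mi <- idx[[mother[i]]]
    kids[[fi]] <- c(kids[[fi]], i)
    kids[[mi]] <- c(kids[[mi]], i)
  }
  queue <- idx[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(idx, out)
    stop(sprintf("pedigree cycle in family %s involving: %s",
                 famID, paste(id[cyc], collapse = ", ")))
  }
  out
}

#' Read pedigrees from a PED/FAM-style file
#'
#' Parses a whitespace-delimited file with columns FID, IID, PAT, MAT, SEX
#' (\code{0} = missing parent, sex 1 = male / 2 = female); lines starting with
#' \code{#} are comments. One [Pedigree-class] is returned per family, members
#' topologically sorted on load so unordered files are accepted.
#'
#' Individual ids must be unique across the whole file; an id appearing in two
#' families is rejected.
#'
#' @param path file path.
#' @return named list of [Pedigree-class] objects (names = family ids).
#' @seealso [writePedigrees()]
#' @export
readPedigrees <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = c("fid", "iid", "pat", "mat", "sex"))
  key <- paste(tab$fid, tab$iid)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (family, individual) id: %s", key[duplicated(key)][1L]))
  if (anyDuplicated(tab$iid))
    stop(sprintf("individual id '%s' appears in more than one family",
                 tab$iid[duplicated(tab$iid)][1L]))
  peds <- lapply(split(tab, tab$fid), function(d)
    Pedigree(d$fid[1L], d$iid, d$pat, d$mat, as.integer(d$sex)))
  peds[unique(tab$fid)]
}

#' Write pedigrees to a PED/FAM-style file
#'
#' @param peds list of [Pedigree-class] objects.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePedigrees <- function(peds, path) {
  rows <- lapply(peds, function(p) {
    m <- members(p)
    data.frame(fid = famID(p), iid = m$id,
               pat = ifelse(is.na(m$father), "0", m$father),
               mat = ifelse(is.na(m$mother), "0", m$mother),
               sex = ifelse(m$sex == "male", 1L, 2L))
  })
  utils::write.table(do.call(rbind, rows), path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname Pedigree-class
#' @export
setMethod("famID", "Pedigree", function(x) x@famID)

#' @rdname Pedigree-class
#' @export
setMethod("members", "Pedigree", function(x) x@members)

#' @rdname Pedigree-class
#' @export
setMethod("nMembers", "Pedigree", function(x) nrow(x@members))

#' @rdname Pedigree-class
#' @export
setMethod("founderIDs", "Pedigree", function(x) x@members$id[x@members$founder])

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree %s: %d members (%d founders, %d descendants)\n",
              object@famID, nrow(m), sum(m$founder), sum(!m$founder)))
})

#' @rdname kinship
#' @export
setMethod("kinship", "Pedigree", function(ped) {
  m <- members(ped)
  n <- nrow(m)
  phi <- matrix(0, n, n, dimnames = list(m$id, m$id))
  pos <- seq_len(n)
  names(pos) <- m$id
  for (i in seq_len(n)) {
    if (m$founder[i]) {
      phi[i, i] <- 0.5
      # founders unrelated to all earlier members
    } else {
      f <- pos[[m$father[i]]]
      mo <- pos[[m$mother[i]]]
      phi[i, i] <- 0.5 * (1 + phi[f, mo])
      for (j in seq_len(i - 1L)) {
        v <- 0.5 * (phi[f, j] + phi[mo, j])
        phi[i, j] <- v
        phi[j, i] <- v
      }
    }
  }
  phi
})
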