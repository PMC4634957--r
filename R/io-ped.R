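# 6-column PED pedigree files: family, individual, father, mother, sex,
# phenotype (1 = unaffected, 2 = affected, 0 = unknown). "0" in a parent
# column means the parent is not in the file.

#' Read a pedigree file
#'
#' @param path Path to a whitespace-delimited 6-column PED file.
#' @param consanguinity Optional named numeric vector of consanguinity
#'   degrees per family (e.g. `c(A = 5, B = 3)`); attached as an attribute.
#' @return A data.frame of class `pedigree` with columns `family`, `id`,
#'   `father`, `mother` (`NA` when absent), `sex` (`"M"`, `"F"`, `NA`) and
#'   `affected` (`"yes"`, `"no"`, `"unknown"`).
#' @export
read_ped <- function(path, consanguinity = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 6L) {
    stop(path, ": expected 6 columns, found ", ncol(raw), call. = FALSE)
  }
  names(raw) <- c("family", "id", "father", "mother", "sex", "phenotype")
  ped <- data.frame(
    family = raw$family,
    id = raw$id,
    father = ifelse(raw$father == "0", NA_character_, raw$father),
    mother = ifelse(raw$mother == "0", NA_character_, raw$mother),
    sex = c("1" = "M", "2" = "F")[raw$sex],
    affected = c("1" = "no", "2" = "yes", "0" = "unknown")[raw$phenotype],
    stringsAsFactors = FALSE
  )
  if (any(is.na(ped$affected))) {
    bad <- which(is.na(ped$affected))[1L]
    stop_format(path, bad, paste0("invalid phenotype code '", raw$phenotype[bad], "'"))
  }
  validate_pedigree(ped, path = path)
  attr(ped, "consanguinity") <- consanguinity
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped, path = "<pedigree>") {
  if (anyDuplicated(ped$id)) {
    stop(path, ": duplicate individual id ", ped$id[duplicated(ped$id)][1L],
         call. = FALSE)
  }
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    missing_parent <- !is.na(ref) & !(ref %in% ped$id)
    if (any(missing_parent)) {
      stop(path, ": ", col, " '", ref[missing_parent][1L], "' of individual ",
           ped$id[missing_parent][1L], " is not in the file", call. = FALSE)
    }
    same_family <- is.na(ref) | ped$family[match(ref, ped$id)] == ped$family
    if (!all(same_family)) {
      stop(path, ": ", col, " of ", ped$id[!same_family][1L],
           " belongs to a different family", call. = FALSE)
    }
  }
  # No individual may be its own ancestor.
  parent_of <- function(id) {
    row <- ped[ped$id == id, , drop = FALSE]
    stats::na.omit(c(row$father, row$mother))
  }
  for (id in ped$id) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier) {
        stop(path, ": pedigree cycle involving individual ", id, call. = FALSE)
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  invisible(ped)
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped A `pedigree` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex_code <- c(M = "1", F = "2")[ped$sex]
  sex_code[is.na(sex_code)] <- "0"
  pheno <- c(no = "1", yes = "2", unknown = "0")[ped$affected]
  lines <- paste(ped$family, ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 sex_code, pheno, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d families (%d affected)\n",
              nrow(x), length(unique(x$family)), sum(x$affected == "yes")))
  print(as.data.frame(x), ...)
  invisible(x)
}
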