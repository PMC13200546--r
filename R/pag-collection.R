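#' Construct a PAG (pathway / annotated gene list / gene signature)
#'
#' A PAG is a named gene set: an opaque identifier, a short name, an optional
#' free-text description, and a set of gene identifiers. Gene identifiers are
#' treated as opaque strings (no species or identifier-type normalization);
#' they are whitespace-trimmed and deduplicated, and compared case-sensitively.
#'
#' @param id Non-empty identifier string.
#' @param genes Character vector of gene identifiers.
#' @param name Short label; defaults to `id`.
#' @param description Free text, may be empty.
#' @return An object of class `pag`.
#' @export
pag <- function(id, genes, name = id, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(trimws(id))) {
    stop("PAG 'id' must be a single non-empty string", call. = FALSE)
  }
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  genes <- unique(genes)
  structure(
    list(id = trimws(id), name = name,
         description = if (is.na(description)) "" else as.character(description),
         genes = genes),
    class = "pag"
  )
}

#' @export
print.pag <- function(x, ...) {
  cat(sprintf("<pag> %s (%d genes)\n", x$id, length(x$genes)))
  invisible(x)
}

#' Construct a collection of PAGs
#'
#' @param pags List of [pag()] objects (order is preserved).
#' @param universe Optional explicit background gene universe. Defaults to the
#'   union of all member gene sets. Must contain every member gene.
#' @return An object of class `pag_collection` with elements `pags` (named
#'   list, in input order) and `universe` (character vector).
#' @export
pag_collection <- function(pags, universe = NULL) {
  if (length(pags) == 0L) stop("collection must contain at least one PAG", call. = FALSE)
  ids <- vapply(pags, function(p) p$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate PAG id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  members <- unique(unlist(lapply(pags, function(p) p$genes), use.names = FALSE))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- unique(trimws(as.character(universe)))
    missing <- setdiff(members, universe)
    if (length(missing)) {
      stop("universe is missing member gene(s), e.g. ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
  }
  names(pags) <- ids
  structure(list(pags = pags, universe = universe), class = "pag_collection")
}

#' @export
print.pag_collection <- function(x, ...) {
  sizes <- vapply(x$pags, function(p) length(p$genes), integer(1))
  cat(sprintf("<pag_collection> %d PAGs, universe of %d genes (set sizes %d-%d)\n",
              length(x$pags), length(x$universe), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.pag_collection <- function(x) length(x$pags)

#' PAG ids of a collection
#' @param x A `pag_collection`.
#' @return Character vector of ids in collection order.
#' @export
pag_ids <- function(x) {
  stopifnot(inherits(x, "pag_collection"))
  names(x$pags)
}

#' Read a gene-set collection from a GMT file
#'
#' One gene set per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' The description field may be empty but must be present (at least three
#' tab-separated fields per line). Duplicate genes within a line are
#' collapsed; the universe is the union of all member genes.
#'
#' @param path Path to a GMT file.
#' @return A [pag_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  pags <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d (%d field(s), need >= 3)",
                   lineno[i], length(fields)), call. = FALSE)
    }
    pags[[i]] <- pag(id = fields[1], name = fields[1],
                     description = fields[2], genes = fields[-(1:2)])
  }
  pag_collection(pags)
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: writing and re-reading preserves membership and
#' ordering exactly.
#'
#' @param collection A `pag_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pag_collection"))
  lines <- vapply(collection$pags, function(p) {
    paste(c(p$id, p$description, p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read PAG descriptions from a two-column TSV
#'
#' Column 1 is the PAG id, column 2 the free-text description. Ids absent
#' from the file are simply absent from the mapping (callers treat a missing
#' id as an empty description). A header line `id<TAB>description` is
#' recognized and skipped.
#'
#' @param path Path to a TSV file.
#' @return Named character vector (id -> text).
#' @export
read_descriptions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[1]), "id\tdescription")) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  txt <- vapply(parts, function(p) {
    if (length(p) < 2L) "" else paste(p[-1], collapse = "\t")
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in description table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(txt, ids)
}

#' Write PAG descriptions as a two-column TSV
#'
#' @param descriptions Named character vector (id -> text).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptions <- function(descriptions, path) {
  writeLines(c("id\tdescription",
               paste(names(descriptions), descriptions, sep = "\t")), path)
  invisible(path)
}

#' Descriptions carried by a collection itself
#' @param x A `pag_collection`.
#' @return Named character vector (id -> description).
#' @export
collection_descriptions <- function(x) {
  stopifnot(inherits(x, "pag_collection"))
  vapply(x$pags, function(p) p$description, character(1))
}
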