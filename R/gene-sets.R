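#' Gene set constructor
#'
#' A named set of gene symbols, e.g. the extracellular-matrix (ECM) pathway.
#' Symbols are uppercased and de-duplicated; `m` is the set cardinality.
#'
#' @param name pathway name.
#' @param genes character vector of gene symbols.
#' @return object of class `"gene_set"` with fields `name`, `genes`, `m`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(normalize_symbols(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) < 1) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes,
                 m = length(genes)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, x$m))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-delimited GMT format: one gene set per line with fields
#' name, description, then gene symbols. Duplicate symbols within a line are
#' collapsed.
#'
#' @param path path to a GMT file.
#' @return a named list of [gene_set] objects (class
#'   `"gene_set_collection"`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", k, ": expected >= 3 tab-separated fields, ",
           "got ", length(fields))
    nm[k] <- fields[1]
    sets[[k]] <- gene_set(fields[1], fields[-(1:2)])
  }
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection named list of [gene_set] objects.
#' @param path output file.
#' @param description description field written for every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(collection, function(gs)
    paste(c(gs$name, description, gs$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x)))
  invisible(x)
}
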