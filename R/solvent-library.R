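# Curated table of literature solvent HSPs, plus readers/writers for
# user-supplied tables.  Solvent HSPs are treated as frozen physical
# constants shipped with the package; each row records its source tag.

# Canonical form used for all name matching: lower case, trimmed, internal
# whitespace collapsed.
canonical_name <- function(x) {
  gsub("\\s+", " ", trimws(tolower(as.character(x))))
}

#' Load a solvent HSP library
#'
#' Reads a CSV of solvent Hansen parameters.  With no `path` the bundled
#' literature library is returned: the 21 solvents used for polyphenol
#' sphere determination (water, four alcohols plus 1-butanol, three ketones,
#' acetonitrile, five esters, two alkanes, two cycloalkanes, diisopropyl
#' ether and p-xylene), with 25 degrees C handbook values.
#'
#' @param path CSV file with header
#'   `name,delta_d,delta_p,delta_h[,synonyms,source]`; synonyms are
#'   semicolon-separated.  `NULL` (default) loads the bundled library.
#' @return A data frame of class `"solvent_library"` with columns `name`,
#'   `delta_d`, `delta_p`, `delta_h`, `synonyms`, `source`, and a
#'   `"version"` attribute.
#' @examples
#' lib <- load_solvent_library()
#' lookup_solvent(lib, "MEK")
#' @export
load_solvent_library <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin) {
    path <- system.file("extdata", "hansen_solvents.csv", package = "hspfit")
  }
  if (!file.exists(path) || !nzchar(path)) {
    stop_input(sprintf("solvent library file not found: '%s'", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop_input(paste0("malformed solvent CSV: ", conditionMessage(e))))
  required <- c("name", "delta_d", "delta_p", "delta_h")
  if (!all(required %in% names(df))) {
    stop_input(paste0("solvent CSV must have columns ",
                      paste(required, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    stop_input("solvent library is empty")
  }
  if (!"synonyms" %in% names(df)) df$synonyms <- ""
  if (!"source" %in% names(df)) df$source <- ""
  df$synonyms[is.na(df$synonyms)] <- ""
  df$source[is.na(df$source)] <- ""
  for (col in c("delta_d", "delta_p", "delta_h")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(!is.finite(v))) {
      stop_input(sprintf("non-numeric or missing values in column '%s'", col))
    }
    if (any(v < 0)) {
      stop_input(sprintf("negative Hansen parameter in column '%s'", col))
    }
    df[[col]] <- v
  }
  df$name <- canonical_name(df$name)
  if (anyDuplicated(df$name)) {
    stop_input(paste0("duplicate solvent names: ",
                      paste(unique(df$name[duplicated(df$name)]), collapse = ", ")))
  }
  # Every name and synonym must resolve to exactly one record.
  keys <- library_keys(df)
  if (anyDuplicated(keys$key)) {
    dup <- unique(keys$key[duplicated(keys$key)])
    stop_input(paste0("ambiguous solvent names/synonyms: ",
                      paste(dup, collapse = ", ")))
  }
  df <- df[, c("name", "delta_d", "delta_p", "delta_h", "synonyms", "source")]
  attr(df, "version") <- if (builtin) {
    paste0("hspfit-builtin-", as.character(utils::packageVersion("hspfit")))
  } else {
    paste0("user-", basename(path))
  }
  class(df) <- c("solvent_library", "data.frame")
  df
}

# name/synonym -> row index map
library_keys <- function(df) {
  syn <- strsplit(df$synonyms, ";", fixed = TRUE)
  keys <- lapply(seq_len(nrow(df)), function(i) {
    s <- canonical_name(syn[[i]])
    unique(c(df$name[i], s[nzchar(s)]))
  })
  data.frame(key = unlist(keys),
             idx = rep(seq_len(nrow(df)), lengths(keys)),
             stringsAsFactors = FALSE)
}

#' Look up a solvent by name or synonym
#'
#' Matching is case- and whitespace-insensitive; common abbreviations (MEK,
#' MiBK, IPAc, ...) resolve through the synonym column.
#'
#' @param lib A [load_solvent_library()] result.
#' @param name Solvent name or synonym.
#' @return A list with fields `name`, `hsp` (an [hsp()] triple), `synonyms`
#'   (character vector) and `source`.
#' @export
lookup_solvent <- function(lib, name) {
  stopifnot(inherits(lib, "solvent_library"))
  key <- canonical_name(name)
  if (length(key) != 1L || !nzchar(key)) {
    stop_input("solvent name must be a single non-empty string")
  }
  keys <- library_keys(lib)
  hit <- keys$idx[keys$key == key]
  if (length(hit) == 0L) {
    near <- unique(keys$key[utils::adist(key, keys$key) <= 3])
    hint <- if (length(near)) {
      paste0("; nearest matches: ", paste(utils::head(near, 3), collapse = ", "))
    } else ""
    stop_input(sprintf("unknown solvent '%s'%s", name, hint))
  }
  i <- hit[1]
  syn <- canonical_name(strsplit(lib$synonyms[i], ";", fixed = TRUE)[[1]])
  list(name = lib$name[i],
       hsp = hsp(lib$delta_d[i], lib$delta_p[i], lib$delta_h[i]),
       synonyms = syn[nzchar(syn)],
       source = lib$source[i])
}

# Resolve a character vector of solvent names to an n x 3 coordinate matrix.
resolve_hsp_matrix <- function(lib, names) {
  m <- t(vapply(names, function(nm) unclass(lookup_solvent(lib, nm)$hsp),
                numeric(3)))
  dimnames(m) <- list(names, c("delta_d", "delta_p", "delta_h"))
  m
}

#' Write a solvent library to CSV
#'
#' Round-trips with [load_solvent_library()]: reloading the written file
#' yields a content-identical library.
#'
#' @param lib A `"solvent_library"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solvent_library <- function(lib, path) {
  stopifnot(inherits(lib, "solvent_library"))
  utils::write.csv(as.data.frame(lib), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.solvent_library <- function(x, ...) {
  cat(sprintf("Solvent HSP library: %d solvents (version %s)\n",
              nrow(x), attr(x, "version") %||% "?"))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
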