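#' Read a TPS landmark file
#'
#' Minimal reader for the classic TPS layout: an `LM=k` line, k
#' whitespace-separated coordinate lines, and an `ID=name` line per specimen
#' (`SCALE=` lines are applied multiplicatively, other keys ignored).
#'
#' @param path Path to a TPS file.
#' @return Long tibble (`specimen`, `landmark`, `x`, `y`).
#' @export
pr_read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list(); coords <- NULL; k <- NA_integer_; id <- NULL; scl <- 1
  flush <- function() {
    if (is.null(coords)) return()
    if (nrow(coords) != k) stop("TPS: LM count mismatch for '", id, "'", call. = FALSE)
    out[[length(out) + 1L]] <<- tibble::tibble(
      specimen = if (is.null(id)) paste0("spec", length(out) + 1L) else id,
      landmark = seq_len(k), x = coords[, 1] * scl, y = coords[, 2] * scl)
  }
  for (ln in lines) {
    if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      flush(); coords <- matrix(numeric(0), 0, 2)
      k <- as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE))
      id <- NULL; scl <- 1
    } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
      id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
    } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
      scl <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
    } else if (grepl("^[-0-9.]", ln)) {
      xy <- as.numeric(strsplit(ln, "\\s+")[[1]])
      coords <- rbind(coords, xy[1:2])
    }
  }
  flush()
  if (!length(out)) stop("no specimens in TPS file", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Write landmarks to a TPS file
#'
#' @param landmarks Long tibble (`specimen`, `landmark`, `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
pr_write_tps <- function(landmarks, path) {
  d <- tibble::as_tibble(landmarks)
  con <- file(path, "w"); on.exit(close(con))
  for (s in unique(d$specimen)) {
    ds <- d[d$specimen == s, ]
    ds <- ds[order(ds$landmark), ]
    writeLines(c(paste0("LM=", nrow(ds)),
                 sprintf("%.10g %.10g", ds$x, ds$y),
                 paste0("ID=", s)), con)
  }
  invisible(path)
}

#' Read/write a trait table as TSV
#'
#' Header row, tip names in the first column, one numeric column per trait.
#'
#' @param path File path.
#' @return `pr_read_traits()`: a tibble; `pr_write_traits()`: `path`,
#'   invisibly.
#' @export
pr_read_traits <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(d)
}

#' @rdname pr_read_traits
#' @param traits Tibble, first column = tip names.
#' @export
pr_write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# JSON run manifest written next to every CLI output set
write_manifest <- function(dir, command, params, files, seed) {
  manifest <- list(
    command = command,
    parameters = params,
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("phyloridge")),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
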