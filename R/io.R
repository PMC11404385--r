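# Delimited-matrix I/O. TSV is the canonical dialect (tab separator, '.'
# decimal, header row of feature names, first column of sample IDs); CSV is
# accepted on read. All numbers are written at 17 significant digits so a
# write -> read round trip is bit-stable.

.read_delim_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric values in ", path, ", column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  M
}

#' Write a numeric matrix as TSV
#'
#' Tab-separated with a header row of column names and a leading sample-ID
#' column; values at 17 significant digits.
#'
#' @param m Matrix (row names used as sample IDs).
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(format(m, digits = 17, trim = TRUE, scientific = TRUE), 1,
                paste, collapse = "\t")
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read an aligned (x, y, z) data bundle
#'
#' Reads three delimited text files (TSV or CSV; header row of feature
#' names, first column of sample IDs), aligns \code{y} and \code{z} to the
#' sample order of \code{x} by ID, and validates: shared IDs, no missing
#' values, numeric cells, and 0/1 coding for a bernoulli outcome.
#'
#' @param x_path,y_path,z_path File paths (\code{z} is a one-column matrix
#'   file).
#' @param family Declared outcome family.
#' @return Object of class \code{"data_bundle"}: matrices \code{x},
#'   \code{y}, vector \code{z}, the \code{family}, and \code{centers}
#'   (column means of x, y and, for gaussian, z).
#' @export
read_bundle <- function(x_path, y_path, z_path,
                        family = c("gaussian", "bernoulli")) {
  family <- match.arg(family)
  x <- .read_delim_matrix(x_path)
  y <- .read_delim_matrix(y_path)
  zm <- .read_delim_matrix(z_path)
  align <- function(M, name) {
    missing <- setdiff(rownames(x), rownames(M))
    extra <- setdiff(rownames(M), rownames(x))
    if (length(missing) || length(extra))
      stop("sample IDs of ", name, " do not match x; missing: ",
           paste(missing, collapse = ","), "; unmatched: ",
           paste(extra, collapse = ","))
    M[rownames(x), , drop = FALSE]
  }
  y <- align(y, "y")
  zm <- align(zm, "z")
  z <- stats::setNames(zm[, 1L], rownames(zm))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("missing values are not supported")
  if (family == "bernoulli" && !all(z %in% c(0, 1)))
    stop("bernoulli outcome must be coded 0/1; found: ",
         paste(unique(z[!z %in% c(0, 1)]), collapse = ","))
  structure(list(x = x, y = y, z = z, family = family,
                 centers = list(x = colMeans(x), y = colMeans(y),
                                z = if (family == "gaussian") mean(z) else 0)),
            class = "data_bundle")
}

#' Serialize a parameter set to delimited text
#'
#' One TSV file per matrix/vector plus a flat key-value manifest holding
#' dimensions, family and scalars. A write -> read round trip reproduces
#' the parameters to 17 significant digits.
#'
#' @param params A \code{po2pls_params} object.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_params <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("W", "C", "Wo", "Co"))
    write_matrix_tsv(params[[nm]], file.path(dir, paste0(nm, ".tsv")))
  vecs <- c("B", "St", "Sto", "Suo", "Sh", "a", "b")
  for (nm in vecs)
    write_matrix_tsv(matrix(params[[nm]], ncol = 1,
                            dimnames = list(NULL, nm)),
                     file.path(dir, paste0(nm, ".tsv")))
  d <- params$dims
  man <- c(family = params$family,
           p = d$p, q = d$q, K = d$K, Kx = d$Kx, Ky = d$Ky,
           sig_e2 = format(params$sig_e2, digits = 17),
           sig_f2 = format(params$sig_f2, digits = 17),
           a0 = format(params$a0, digits = 17),
           sig_g2 = if (is.null(params$sig_g2)) "NA"
                    else format(params$sig_g2, digits = 17))
  writeLines(paste(names(man), man, sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_params
#' @export
read_params <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("key", "value"))
  kv <- stats::setNames(man$value, man$key)
  rd <- function(nm) unname(.read_delim_matrix(file.path(dir, paste0(nm, ".tsv"))))
  sig_g2 <- if (kv[["sig_g2"]] == "NA") NULL else as.numeric(kv[["sig_g2"]])
  po2pls_params(W = rd("W"), C = rd("C"), Wo = rd("Wo"), Co = rd("Co"),
                B = drop(rd("B")), St = drop(rd("St")), Sto = drop(rd("Sto")),
                Suo = drop(rd("Suo")), Sh = drop(rd("Sh")),
                sig_e2 = as.numeric(kv[["sig_e2"]]),
                sig_f2 = as.numeric(kv[["sig_f2"]]),
                a = drop(rd("a")), b = drop(rd("b")),
                a0 = as.numeric(kv[["a0"]]), sig_g2 = sig_g2,
                family = kv[["family"]])
}
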