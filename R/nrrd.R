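#' Write a grid object to an NRRD file
#'
#' Serializes a [dose_grid()] (scalar volume), [structure_mask()] (0/1 uchar
#' volume) or [build_dvf()] field (3-component volume, component axis first)
#' as NRRD 0004 with either raw little-endian or ascii text encoding. Only
#' the dialect written here (plus axis-aligned `space directions`) is
#' understood by [read_nrrd()]; it is sufficient to exchange volumes with
#' common medical-image tools.
#'
#' @param x object to write.
#' @param path output file path.
#' @param encoding `"raw"` (binary, default) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  if (inherits(x, "dose_grid")) {
    arr <- x$values; type <- "double"; content <- "dose"
  } else if (inherits(x, "structure_mask")) {
    arr <- array(as.integer(x$values), dim = dim(x$values))
    type <- "unsigned char"; content <- paste0("mask:", x$name)
  } else if (inherits(x, "deformation_field")) {
    # component axis first, as is conventional for vector NRRDs
    arr <- aperm(x$vectors, c(4, 1, 2, 3))
    type <- "double"; content <- "dvf"
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  nd <- length(dim(arr))
  dirs <- diag(x$spacing)
  dir_str <- apply(dirs, 1, function(r) sprintf("(%.10g,%.10g,%.10g)",
                                                r[1], r[2], r[3]))
  if (nd == 4L) dir_str <- c("none", dir_str)
  header <- c(
    "NRRD0004",
    "# generated by tomodrift",
    paste0("type: ", type),
    paste0("dimension: ", nd),
    "space dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("space directions: ", paste(dir_str, collapse = " ")),
    "kinds: " %+% if (nd == 4L) "vector domain domain domain" else
      "domain domain domain",
    paste0("endian: ", "little"),
    paste0("encoding: ", encoding),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            x$origin[1], x$origin[2], x$origin[3]),
    paste0("content: ", content),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (encoding == "raw") {
    if (type == "double") {
      writeBin(as.numeric(arr), con, size = 8, endian = "little")
    } else {
      writeBin(as.raw(arr), con)
    }
  } else {
    writeLines(paste(format(as.vector(arr), digits = 17, trim = TRUE,
                            scientific = NA), collapse = " "), con)
  }
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)

#' Read an NRRD file written by this package
#'
#' @param path NRRD file path.
#' @param name structure name to assign when reading a mask whose header does
#'   not carry one.
#' @return a `dose_grid`, `structure_mask` or `deformation_field`, chosen
#'   from the header's content/size information.
#' @export
read_nrrd <- function(path, name = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+: ", line))
    if (length(kv) == 0L) next
    key <- sub(": $", "", kv)
    fields[[key]] <- sub("^[^:]+: ", "", line)
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  type <- fields$type
  encoding <- fields$encoding
  origin <- parse_nrrd_vector(fields$`space origin`)
  dirs <- regmatches(fields$`space directions`,
                     gregexpr("\\(([^)]*)\\)", fields$`space directions`))[[1]]
  spacing <- vapply(seq_along(dirs), function(i) {
    v <- parse_nrrd_vector(dirs[i])
    if (abs(v[i]) < max(abs(v)) - 1e-9)
      stop("only axis-aligned space directions are supported")
    sqrt(sum(v^2))
  }, numeric(1))
  n <- prod(sizes)
  if (encoding == "raw") {
    if (type == "double") {
      vec <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    } else if (type %in% c("unsigned char", "uchar", "uint8")) {
      vec <- as.integer(readBin(con, "raw", n = n))
    } else stop("unsupported NRRD type: ", type)
  } else if (encoding %in% c("text", "txt", "ascii")) {
    txt <- readLines(con)
    toks <- strsplit(paste(txt, collapse = " "), "\\s+")[[1]]
    vec <- as.numeric(toks[nzchar(toks)])
  } else stop("unsupported NRRD encoding: ", encoding)
  if (length(vec) != n)
    stop("NRRD data length mismatch: expected ", n, ", got ", length(vec))
  content <- fields$content %||% ""
  if (length(sizes) == 4L) {
    arr <- array(vec, dim = sizes)
    vectors <- aperm(arr, c(2, 3, 4, 1))
    return(deformation_field(vectors, spacing = spacing, origin = origin))
  }
  arr <- array(vec, dim = sizes)
  if (startsWith(content, "mask") ||
      type %in% c("unsigned char", "uchar", "uint8")) {
    nm <- name %||% sub("^mask:", "", content)
    if (identical(nm, "")) nm <- "structure"
    return(structure_mask(arr != 0, spacing = spacing, origin = origin,
                          name = nm))
  }
  dose_grid(arr, spacing = spacing, origin = origin)
}

parse_nrrd_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", trimws(s)), ",")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
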