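#' Run container: on-disk layout for one simulated examination
#'
#' One directory per examination, with subdirectories named after the stages
#' of an MPI measurement-data layout: \code{acquisition} (scanner
#' parameters), \code{calibration} (system matrix), \code{measurement} (raw
#' frames and background), \code{truth} (phantom ground truth),
#' \code{reconstruction} (volume series) and \code{analysis} (derived
#' tables). Numeric and complex arrays are stored as raw little-endian
#' doubles (bit-exact round trip); everything else goes into a JSON manifest
#' per node. A schema version is written and checked on read.
#'
#' @name run_container
NULL

.container_schema <- list(format = "mpiangio-run", version = "1.0")

#' Write a run container to disk
#'
#' @param run Named list of stage objects (any nesting of lists, numeric /
#'   complex arrays, data frames, scalars).
#' @param path Target directory (created; must not already contain a run).
#' @return \code{path}, invisibly.
#' @export
write_run_container <- function(run, path) {
  stopifnot(is.list(run))
  if (dir.exists(file.path(path, "schema.json"))) {
    stop("refusing to overwrite existing container", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.container_schema, file.path(path, "schema.json"),
                       auto_unbox = TRUE)
  write_node(run, path)
  invisible(path)
}

#' Read a run container from disk
#'
#' @param path Container directory.
#' @return The reconstructed nested list.
#' @export
read_run_container <- function(path) {
  sf <- file.path(path, "schema.json")
  if (!file.exists(sf)) stop("not a run container: ", path, call. = FALSE)
  schema <- jsonlite::read_json(sf, simplifyVector = TRUE)
  if (!identical(schema$format, .container_schema$format)) {
    stop("unknown container format: ", schema$format, call. = FALSE)
  }
  major <- sub("\\..*$", "", schema$version)
  if (major != sub("\\..*$", "", .container_schema$version)) {
    stop("unsupported container major version: ", schema$version,
         call. = FALSE)
  }
  read_node(path)
}

# ---- recursive (de)serialization -----------------------------------------

write_node <- function(x, dir) {
  stopifnot(is.list(x), !is.null(names(x)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(class = class(x), fields = list())
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) {
      manifest$fields[[nm]] <- list(kind = "null")
    } else if (is.data.frame(v)) {
      # columns serialized individually so numeric columns round-trip
      # bit-exactly through the binary path
      write_node(as.list(v), file.path(dir, nm))
      manifest$fields[[nm]] <- list(kind = "data.frame",
                                    class = class(v),
                                    columns = names(v),
                                    nrow = nrow(v))
    } else if (is.list(v)) {
      write_node(v, file.path(dir, nm))
      manifest$fields[[nm]] <- list(kind = "node")
    } else if (is.complex(v)) {
      con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
      writeBin(c(as.vector(Re(v)), as.vector(Im(v))), con, size = 8,
               endian = "little")
      close(con)
      manifest$fields[[nm]] <- list(kind = "complex",
                                    dim = dim_or_len(v),
                                    dimnames = !is.null(dimnames(v)))
    } else if (is.double(v)) {
      # all doubles go through the binary path: JSON text would round
      con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
      writeBin(unname(as.vector(v)), con, size = 8, endian = "little")
      close(con)
      manifest$fields[[nm]] <- list(kind = "double", dim = dim_or_len(v),
                                    names = names(v))
    } else {
      # scalars and short atomic vectors: full-precision JSON in manifest
      manifest$fields[[nm]] <- list(kind = "value",
                                    type = typeof(v),
                                    dim = dim_or_len(v),
                                    names = names(v),
                                    data = I(unname(as.vector(v))))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
}

read_node <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list()
  fields <- manifest$fields
  for (nm in names(fields)) {
    f <- fields[[nm]]
    out[[nm]] <- switch(f$kind,
      "null" = NULL,
      "node" = read_node(file.path(dir, nm)),
      "data.frame" = {
        cols <- read_node(file.path(dir, nm))
        df <- as.data.frame(cols[unlist(f$columns)],
                            stringsAsFactors = FALSE)
        class(df) <- unlist(f$class)
        df
      },
      "complex" = {
        n <- prod(f$dim)
        con <- file(file.path(dir, paste0(nm, ".bin")), "rb")
        vals <- readBin(con, "double", n = 2L * n, size = 8,
                        endian = "little")
        close(con)
        z <- complex(real = vals[seq_len(n)], imaginary = vals[n + seq_len(n)])
        set_dims(z, f$dim)
      },
      "double" = {
        con <- file(file.path(dir, paste0(nm, ".bin")), "rb")
        vals <- readBin(con, "double", n = prod(f$dim), size = 8,
                        endian = "little")
        close(con)
        vals <- set_dims(vals, f$dim)
        if (!is.null(f$names)) names(vals) <- unlist(f$names)
        vals
      },
      "value" = {
        v <- f$data
        v <- switch(f$type,
                    integer = as.integer(v),
                    double = as.double(v),
                    logical = as.logical(v),
                    character = as.character(v),
                    v)
        v <- set_dims(v, f$dim)
        if (!is.null(f$names)) names(v) <- unlist(f$names)
        v
      },
      stop("unknown field kind: ", f$kind, call. = FALSE)
    )
  }
  cls <- unlist(manifest$class)
  if (!identical(cls, "list")) class(out) <- cls
  out
}

dim_or_len <- function(v) {
  if (is.null(dim(v))) length(v) else dim(v)
}

set_dims <- function(v, d) {
  d <- as.integer(unlist(d))
  if (length(d) > 1L) dim(v) <- d
  v
}
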