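#' Write genotypes as a GENEPOP file
#'
#' Long genotype data are written in the classic GENEPOP layout: a title
#' line, one locus name per line, then one \code{Pop} block per population
#' with \code{individual ,  aaabbb} rows of 3-digit allele codes (allele
#' sizes are used directly as codes and must be < 1000).
#'
#' @param gd genotype data frame.
#' @param path output file.
#' @param title first line of the file.
#' @export
write_genepop <- function(gd, path, title = "paleodemog genotypes") {
  gd <- as_genotype_data(gd)
  loci <- unique(gd$locus)
  if (any(gd$allele1 >= 1000 | gd$allele2 >= 1000, na.rm = TRUE))
    stop("allele sizes must be < 1000 for 3-digit GENEPOP codes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, as.character(loci)), con)
  for (p in unique(gd$pop)) {
    writeLines("Pop", con)
    sub <- gd[gd$pop == p, , drop = FALSE]
    for (ind in unique(sub$individual)) {
      r <- sub[sub$individual == ind, , drop = FALSE]
      g <- vapply(loci, function(l) {
        i <- which(r$locus == l)
        if (!length(i) || is.na(r$allele1[i]) || is.na(r$allele2[i]))
          return("000000")
        sprintf("%03d%03d", r$allele1[i], r$allele2[i])
      }, character(1))
      writeLines(paste0(ind, " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GENEPOP file into the long genotype layout
#'
#' Supports the single-line loci-per-line header variant with 3-digit
#' diploid allele codes; \code{000} codes become missing alleles.
#'
#' @param path GENEPOP file.
#' @return genotype data frame.
#' @export
read_genepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) stop("not a GENEPOP file")
  loci <- lines[2:(first_pop - 1)]
  if (length(loci) == 1 && grepl(",", loci)) # comma-separated locus header
    loci <- trimws(strsplit(loci, ",")[[1]])
  out <- list()
  pop_idx <- 0
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { pop_idx <- pop_idx + 1; next }
    parts <- strsplit(lines[i], ",")[[1]]
    ind <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stop("genotype count does not match locus count at line ", i)
    a1 <- as.integer(substr(codes, 1, 3))
    a2 <- as.integer(substr(codes, 4, 6))
    a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
    out[[length(out) + 1]] <- data.frame(
      individual = ind, pop = paste0("pop", pop_idx), locus = loci,
      allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  }
  as_genotype_data(do.call(rbind, out))
}

#' Read or write long genotype CSV files
#'
#' @param gd genotype data frame.
#' @param path CSV file.
#' @name genotype_csv
#' @export
write_genotypes_csv <- function(gd, path) {
  utils::write.csv(as_genotype_data(gd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname genotype_csv
#' @export
read_genotypes_csv <- function(path) {
  as_genotype_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a map as an ESRI ASCII grid
#'
#' Plain-text raster: six header lines (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize}, \code{NODATA_value})
#' followed by the matrix rows north to south.
#'
#' @param map matrix with a \code{"grid"} attribute (row 1 = north).
#' @param path output file.
#' @param nodata value written for NA cells (default -9999).
#' @export
write_ascii_grid <- function(map, path, nodata = -9999) {
  grid <- attr(map, "grid")
  if (is.null(grid)) stop("map has no grid attribute")
  m <- unclass(map)
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", grid$ncol), paste("nrows", grid$nrow),
           paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
           paste("cellsize", grid$cellsize), paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path grid file.
#' @return matrix with a \code{"grid"} attribute; NODATA cells become NA.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("incomplete ASCII grid header")
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "grid") <- list(nrow = hdr$nrows, ncol = hdr$ncols,
                          xll = hdr$xllcorner, yll = hdr$yllcorner,
                          cellsize = hdr$cellsize)
  m
}

#' Write a suitability stack to a directory
#'
#' One ASCII grid per layer plus a \code{manifest.csv} (algorithm, aogcm,
#' period, path, tss).
#'
#' @param stack a \code{"suitability_stack"}.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "suitability_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- stack$layers
  files <- sprintf("%s_%s_%s.asc", lay$algorithm, lay$aogcm, lay$period)
  for (j in seq_len(ncol(stack$values)))
    write_ascii_grid(.layer_map(stack, j), file.path(dir, files[j]))
  man <- cbind(lay, path = files)
  if (!is.null(stack$tss)) {
    key <- paste(lay$algorithm, lay$aogcm)
    man$tss <- stack$tss$tss[match(key, paste(stack$tss$algorithm,
                                              stack$tss$aogcm))]
  }
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Read a suitability stack from a manifest
#'
#' @param manifest path to a \code{manifest.csv} with columns
#'   \code{algorithm}, \code{aogcm}, \code{period}, \code{path} and
#'   optionally \code{tss}; grid paths are relative to the manifest.
#' @return a \code{"suitability_stack"}.
#' @export
read_stack <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  maps <- lapply(file.path(dir, man$path), read_ascii_grid)
  grid <- attr(maps[[1]], "grid")
  values <- vapply(maps, .map_values, numeric(grid$nrow * grid$ncol))
  tss <- if ("tss" %in% names(man))
    unique(man[c("algorithm", "aogcm", "tss")]) else NULL
  suitability_stack(values, man[c("algorithm", "aogcm", "period")], grid, tss)
}
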