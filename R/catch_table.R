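# Catch tables: tidy length-frequency data with per-gear metadata.
#
# A catch_table is a long tibble with columns `gear`, `length_class`, `catch`
# plus two attributes: `gears` (a tibble of gear metadata) and `normalized`
# (whether each gear column has been scaled to sum to one).

#' Declare a set of capture gears
#'
#' Builds the gear-metadata table attached to every [catch_table]. A gear is
#' either a mesh net, identified by its mesh size in mm, or a free-form
#' predator (a capture method with no mesh, e.g. a piscivorous bird).
#'
#' @param gear Character vector of unique gear labels (e.g. `"G14"`, `"GC"`).
#' @param family Character vector, `"mesh"` or `"predator"`, recycled.
#' @param mesh_size Numeric mesh size in mm; must be a finite positive number
#'   for mesh gears and `NA` for predators.
#'
#' @return A tibble with columns `gear`, `family`, `mesh_size`.
#' @examples
#' gear_spec(c("G14", "G38", "GC"),
#'           family = c("mesh", "mesh", "predator"),
#'           mesh_size = c(14, 38, NA))
#' @export
gear_spec <- function(gear, family, mesh_size = NA_real_) {
  gear <- as.character(gear)
  family <- rep_len(as.character(family), length(gear))
  mesh_size <- rep_len(as.numeric(mesh_size), length(gear))
  if (anyDuplicated(gear)) {
    abort(paste0("Duplicated gear ids: ",
                 paste(unique(gear[duplicated(gear)]), collapse = ", ")))
  }
  bad_family <- setdiff(family, c("mesh", "predator"))
  if (length(bad_family)) {
    abort(paste0("Unknown gear family: ", paste(bad_family, collapse = ", ")))
  }
  mesh <- family == "mesh"
  if (any(mesh & (!is.finite(mesh_size) | mesh_size <= 0))) {
    abort("Mesh gears need a finite positive mesh_size (mm).")
  }
  mesh_size[!mesh] <- NA_real_
  tibble::tibble(gear = gear, family = family, mesh_size = mesh_size)
}

#' Infer gear metadata from column labels
#'
#' Labels of the form `"G<number>"` are parsed as mesh nets with the number as
#' mesh size in mm (so `"G21.5"` is a 21.5 mm net). Any other label must be
#' declared explicitly, either through `gears` or by listing it in
#' `predators`.
#'
#' @param ids Character vector of gear labels.
#' @param gears Optional explicit declaration: a tibble as returned by
#'   [gear_spec()], a named list `list(GC = list(family = "predator"))`, or a
#'   path to a YAML file with that structure.
#' @param predators Optional character vector of labels to treat as predators.
#' @return A [gear_spec()] tibble covering every id, in input order.
#' @export
infer_gears <- function(ids, gears = NULL, predators = NULL) {
  decl <- as_gear_decl(gears)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[[k]]
    if (!is.null(decl) && id %in% decl$gear) {
      out[[k]] <- decl[decl$gear == id, ]
    } else if (!is.null(predators) && id %in% predators) {
      out[[k]] <- gear_spec(id, "predator")
    } else if (grepl("^G[0-9]+(\\.[0-9]+)?$", id)) {
      out[[k]] <- gear_spec(id, "mesh", as.numeric(sub("^G", "", id)))
    } else {
      abort(paste0("Cannot infer gear '", id, "': not of the form G<mesh>. ",
                   "Declare it via `gears` or `predators`."))
    }
  }
  dplyr::bind_rows(out)
}

as_gear_decl <- function(gears) {
  if (is.null(gears)) return(NULL)
  if (is.character(gears) && length(gears) == 1 && file.exists(gears)) {
    gears <- yaml::read_yaml(gears)
  }
  if (is.data.frame(gears)) {
    return(gear_spec(gears$gear, gears$family,
                     gears$mesh_size %||% NA_real_))
  }
  if (is.list(gears)) {
    rows <- purrr::imap(gears, function(g, id) {
      gear_spec(id, g$family %||% "mesh", g$mesh_size %||% NA_real_)
    })
    return(dplyr::bind_rows(rows))
  }
  abort("`gears` must be a data frame, a named list or a YAML path.")
}

new_catch_table <- function(data, gears, normalized = FALSE) {
  out <- tibble::as_tibble(data[c("gear", "length_class", "catch")])
  out$gear <- as.character(out$gear)
  out$length_class <- as.numeric(out$length_class)
  out$catch <- as.numeric(out$catch)
  out <- dplyr::arrange(out, match(.data$gear, gears$gear), .data$length_class)
  structure(out,
            gears = gears,
            normalized = isTRUE(normalized),
            class = c("catch_table", class(out)))
}

#' Coerce a data frame to a catch table
#'
#' Accepts either a long layout (columns `gear`, `length_class`, `catch`) or a
#' wide layout (first column the length class in cm, one further column per
#' gear). Every (gear, length class) cell is materialised, missing
#' combinations filled with zero, and the result validated.
#'
#' @param x A data frame in either layout.
#' @inheritParams infer_gears
#' @param normalized Set to `TRUE` if the values are already per-gear
#'   frequencies summing to one.
#' @return A `catch_table`: a long tibble with gear metadata attached.
#' @examples
#' wide <- data.frame(length_class = c(10, 11), G14 = c(5, 46))
#' as_catch_table(wide)
#' @export
as_catch_table <- function(x, gears = NULL, predators = NULL,
                           normalized = FALSE) {
  stopifnot(is.data.frame(x))
  long <- all(c("gear", "length_class", "catch") %in% names(x))
  if (long) {
    dat <- tibble::as_tibble(x)[c("gear", "length_class", "catch")]
    dup <- duplicated(dat[c("gear", "length_class")])
    if (any(dup)) {
      d <- dat[dup, ][1, ]
      abort(paste0("Duplicated (gear, length_class) pair: (",
                   d$gear, ", ", d$length_class, ")."))
    }
    ginfo <- infer_gears(unique(dat$gear), gears, predators)
    if (is.data.frame(gears)) {  # a full declaration fixes the gear order
      ginfo <- ginfo[order(match(ginfo$gear, gears$gear)), ]
    }
  } else {
    ginfo <- infer_gears(setdiff(names(x), names(x)[1]), gears, predators)
    dat <- tidyr::pivot_longer(tibble::as_tibble(x), -1,
                               names_to = "gear", values_to = "catch")
    names(dat)[1] <- "length_class"
  }
  # complete the grid so every gear shares the same ordered length classes
  dat <- tidyr::complete(dat,
                         gear = ginfo$gear,
                         length_class = sort(unique(dat$length_class)),
                         fill = list(catch = 0))
  tab <- new_catch_table(dat, ginfo, normalized)
  validate_catch_table(tab)
}

validate_catch_table <- function(tab) {
  g <- gear_info(tab)
  if (nrow(g) == 0) abort("Catch table has no gears.")
  lc <- length_classes(tab)
  if (length(lc) == 0) abort("Catch table has no length classes.")
  if (any(!is.finite(lc)) || is.unsorted(lc, strictly = TRUE)) {
    abort("Length classes must be finite and strictly increasing.")
  }
  bad <- which(!is.finite(tab$catch) | tab$catch < 0)
  if (length(bad)) {
    b <- tab[bad[1], ]
    abort(paste0("Negative or non-finite catch in cell (gear ", b$gear,
                 ", length class ", b$length_class, "): ", b$catch))
  }
  sums <- catch_matrix(tab)
  csum <- colSums(sums)
  if (any(csum <= 0)) {
    abort(paste0("Gear column(s) with zero total catch: ",
                 paste(names(csum)[csum <= 0], collapse = ", ")))
  }
  if (is_normalized(tab) && any(abs(csum - 1) > 1e-9)) {
    abort("Table is flagged normalized but gear sums deviate from 1.")
  }
  tab
}

#' @export
print.catch_table <- function(x, ...) {
  g <- gear_info(x)
  cat(sprintf("<catch_table> %d length classes x %d gears (%d mesh, %d predator)%s\n",
              length(length_classes(x)), nrow(g),
              sum(g$family == "mesh"), sum(g$family == "predator"),
              if (is_normalized(x)) ", normalized" else ""))
  NextMethod()
}

#' Accessors for catch tables
#'
#' `gear_info()` returns the gear-metadata tibble, `length_classes()` the
#' ordered vector of length classes (cm), `is_normalized()` the normalization
#' flag and `catch_matrix()` the values as a dense length-class x gear matrix.
#'
#' @param tab A [catch_table][as_catch_table].
#' @name catch_table-accessors
NULL

#' @rdname catch_table-accessors
#' @export
gear_info <- function(tab) attr(tab, "gears")

#' @rdname catch_table-accessors
#' @export
length_classes <- function(tab) sort(unique(tab$length_class))

#' @rdname catch_table-accessors
#' @export
is_normalized <- function(tab) isTRUE(attr(tab, "normalized"))

#' @rdname catch_table-accessors
#' @export
catch_matrix <- function(tab) {
  lc <- length_classes(tab)
  g <- gear_info(tab)$gear
  m <- matrix(0, length(lc), length(g), dimnames = list(lc, g))
  m[cbind(match(tab$length_class, lc), match(tab$gear, g))] <- tab$catch
  m
}

#' Convert catches to per-gear normalised frequencies
#'
#' Divides every gear column by its own total so each gear contributes a
#' length-frequency distribution summing to one. This is the standard
#' preprocessing step before the conditional-likelihood fit: it removes
#' between-gear differences in fishing power and effort, which affect sample
#' size but not the length distribution within a gear's sample.
#'
#' @param tab A [catch_table][as_catch_table] of raw counts.
#' @return A `catch_table` with `is_normalized(tab)` `TRUE`.
#' @examples
#' tab <- as_catch_table(data.frame(length_class = 1:3, G14 = c(5, 46, 30)))
#' normalize_catch(tab)$catch  # 5/81, 46/81, 30/81
#' @export
normalize_catch <- function(tab) {
  stopifnot(inherits(tab, "catch_table"))
  if (is_normalized(tab)) abort("Table is already normalized.")
  tot <- tapply(tab$catch, tab$gear, sum)
  if (any(tot <= 0)) {
    abort(paste0("Cannot normalize gear(s) with zero total: ",
                 paste(names(tot)[tot <= 0], collapse = ", ")))
  }
  out <- tab
  out$catch <- as.numeric(tab$catch / tot[tab$gear])
  attr(out, "normalized") <- TRUE
  validate_catch_table(out)
}

#' Read a catch table from delimited text
#'
#' The delimiter is taken from the extension (`.csv` comma, anything else
#' tab). Files written by [write_catch_table()] carry gear declarations and
#' the normalization flag in `#`-prefixed header comments, which are honoured
#' on reading; otherwise gear families are inferred as in [infer_gears()].
#'
#' @param path File to read.
#' @param layout `"auto"` (detect from the header), `"wide"` or `"long"`.
#' @inheritParams as_catch_table
#' @return A `catch_table`.
#' @export
read_catch_table <- function(path, layout = c("auto", "wide", "long"),
                             gears = NULL, predators = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  meta <- read_header_meta(path)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dat <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  is_long <- all(c("gear", "length_class", "catch") %in% names(dat))
  if (layout == "long" && !is_long) {
    abort("Long layout requires columns gear, length_class, catch.")
  }
  if (layout == "wide" && is_long) {
    abort("File has a long-layout header but layout = \"wide\".")
  }
  gears <- gears %||% meta$gears
  as_catch_table(dat, gears = gears, predators = predators,
                 normalized = meta$normalized %||% FALSE)
}

read_header_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  meta <- list(normalized = NULL, gears = NULL)
  norm <- grep("^#\\s*normalized:", lines, value = TRUE)
  if (length(norm)) {
    meta$normalized <- grepl("true", norm[1], ignore.case = TRUE)
  }
  gl <- grep("^#\\s*gear:", lines, value = TRUE)
  if (length(gl)) {
    rows <- purrr::map(gl, function(l) {
      id <- sub("^#\\s*gear:\\s*(\\S+).*$", "\\1", l)
      fam <- sub("^.*family=(\\S+).*$", "\\1", l)
      ms <- if (grepl("mesh_size=", l)) {
        as.numeric(sub("^.*mesh_size=([0-9.]+).*$", "\\1", l))
      } else NA_real_
      gear_spec(id, fam, ms)
    })
    meta$gears <- dplyr::bind_rows(rows)
  }
  meta
}

#' Write a catch table to delimited text
#'
#' Gear declarations and the normalization flag are stored as `#` header
#' comments so that [read_catch_table()] round-trips the table exactly.
#'
#' @param tab A validated `catch_table`.
#' @param path Destination; `.csv` writes comma-separated, else tab.
#' @param layout `"wide"` (length class column plus one column per gear) or
#'   `"long"` (`gear`, `length_class`, `catch`).
#' @return `path`, invisibly.
#' @export
write_catch_table <- function(tab, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  validate_catch_table(tab)
  g <- gear_info(tab)
  hdr <- c(sprintf("# normalized: %s", tolower(is_normalized(tab))),
           sprintf("# gear: %s family=%s%s", g$gear, g$family,
                   ifelse(g$family == "mesh",
                          sprintf(" mesh_size=%s", format(g$mesh_size)), "")))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (layout == "wide") {
    m <- catch_matrix(tab)
    dat <- tibble::as_tibble(m)
    dat <- dplyr::bind_cols(tibble::tibble(length_class = length_classes(tab)),
                            dat)
  } else {
    dat <- tibble::tibble(gear = tab$gear,
                          length_class = tab$length_class,
                          catch = as.numeric(tab$catch))
  }
  writeLines(hdr, path)
  readr::write_delim(dat, path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' Multi-gear perch length-frequency data
#'
#' Observed numbers of European perch (*Perca fluviatilis*) by 1-cm length
#' class, caught in eight gillnets of increasing mesh size (14-45 mm,
#' columns `G14` ... `G45`) and consumed by Great Cormorants (column `GC`,
#' lengths reconstructed from regurgitated pellets), sampled in the Curonian
#' Lagoon, Lithuania. 34 length classes (2-35 cm), 4663 fish in total of
#' which 3766 were taken by cormorants.
#'
#' @return A `catch_table` of raw counts.
#' @examples
#' tab <- curonian_perch()
#' sum(tab$catch)
#' @export
curonian_perch <- function() {
  path <- system.file("extdata", "curonian_perch.csv", package = "gearselect",
                      mustWork = TRUE)
  read_catch_table(path, layout = "wide")
}
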