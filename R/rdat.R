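#' Assemble an RDAT dataset in memory
#'
#' Container mirroring the RNA Mapping Database flat-file format: one
#' sequence with a numbering offset plus one reactivity row per profile,
#' each annotated with its mutation label and modifier.
#'
#' @param name dataset name.
#' @param construct an [rna_construct()]; its sequence and numbering offset
#'   become the RDAT `SEQUENCE` and `OFFSET` blocks.
#' @param profiles list of [reactivity_profile()]s.  All profile positions
#'   must fall inside the construct.
#' @param structure optional dot-bracket string (defaults to all dots).
#' @param annotations character vector of global `key:value` annotations.
#' @param comments character vector of comment lines.
#' @return Object of class `rdat`.
#' @seealso [read_rdat()], [write_rdat()]
#' @export
rdat <- function(name, construct, profiles, structure = NULL,
                 annotations = character(), comments = character()) {
  stopifnot(inherits(construct, "rna_construct"))
  if (!length(profiles)) stop("rdat needs at least one profile")
  ok <- vapply(profiles, inherits, logical(1), "reactivity_profile")
  if (!all(ok)) stop("profiles must be reactivity_profile objects")
  all_pos <- construct_positions(construct)
  for (p in profiles)
    if (!all(p$positions %in% all_pos))
      stop("profile ", p$mutant_label, " has positions outside the construct")
  if (is.null(structure))
    structure <- strrep(".", nchar(construct$sequence))
  structure(
    list(name = name, construct = construct, profiles = profiles,
         structure = structure, annotations = annotations,
         comments = comments),
    class = "rdat")
}

#' @export
print.rdat <- function(x, ...) {
  cat(sprintf("<rdat> %s: %d profiles over %d nt (offset %+d)\n", x$name,
              length(x$profiles), nchar(x$construct$sequence),
              x$construct$numbering_offset))
  labs <- vapply(x$profiles, `[[`, character(1), "mutant_label")
  cat("  rows:", paste(head(labs, 8L), collapse = ", "),
      if (length(labs) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Read an RDAT chemical-mapping file
#'
#' Parses the tab-delimited block format of the RNA Mapping Database
#' (version 0.2+): `SEQUENCE`, `OFFSET`, `SEQPOS`, `STRUCTURE`,
#' `ANNOTATION`, per-row `ANNOTATION_DATA:n`, `REACTIVITY:n` and
#' `REACTIVITY_ERROR:n` lines.  One [reactivity_profile()] is produced per
#' reactivity row; `mutation:` annotations are joined into the canonical
#' hyphen-separated mutant label (no mutation annotation, or
#' `mutation:WT`, gives `"WT"`), and a per-row `modifier:` annotation
#' overrides the global one.
#'
#' @param path file path.
#' @return Object of class `rdat`; profiles are in `$profiles`.
#' @export
read_rdat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keyed <- function(key) {
    hit <- which(vapply(fields, function(f) length(f) > 0L && f[1] == key,
                        logical(1)))
    hit
  }
  get1 <- function(key, required = FALSE) {
    hit <- keyed(key)
    if (!length(hit)) {
      if (required) stop("RDAT parse error: missing ", key, " block")
      return(NULL)
    }
    fields[[hit[1]]][-1]
  }
  sequence <- get1("SEQUENCE", required = TRUE)
  if (length(sequence) != 1L)
    stop("RDAT parse error at line ", keyed("SEQUENCE")[1],
         ": SEQUENCE must hold one field")
  sequence <- toupper(chartr("Tt", "Uu", sequence))
  offset_field <- get1("OFFSET")
  offset <- if (is.null(offset_field)) 0L else as.integer(offset_field[1])
  name_field <- get1("NAME")
  name <- if (is.null(name_field)) basename(path) else name_field[1]
  structure_str <- get1("STRUCTURE")
  annotations <- get1("ANNOTATION")
  if (is.null(annotations)) annotations <- character()
  comments <- unlist(lapply(keyed("COMMENT"), function(i) fields[[i]][-1]))
  n <- nchar(sequence)

  seqpos_field <- get1("SEQPOS")
  if (is.null(seqpos_field)) {
    seqpos <- seq_len(n) + offset
  } else {
    seqpos <- as.integer(sub("^[A-Za-z]+", "", seqpos_field))
    if (anyNA(seqpos))
      stop("RDAT parse error at line ", keyed("SEQPOS")[1],
           ": cannot parse SEQPOS entries")
  }

  global_modifier <- .annotation_value(annotations, "modifier")
  if (is.null(global_modifier)) global_modifier <- "1M7"

  first <- vapply(fields, function(f) if (length(f)) f[1] else "",
                  character(1))
  row_lines <- grep("^REACTIVITY:[0-9]+$", first)
  parse_row_id <- function(i, prefix)
    as.integer(sub(paste0("^", prefix, ":"), "", fields[[i]][1]))
  profiles <- list()
  for (i in row_lines) {
    id <- parse_row_id(i, "REACTIVITY")
    vals <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (length(vals) != length(seqpos) || anyNA(vals))
      stop("RDAT parse error at line ", i, ": REACTIVITY:", id, " has ",
           length(vals), " values; expected ", length(seqpos))
    ann_hit <- keyed(paste0("ANNOTATION_DATA:", id))
    row_ann <- if (length(ann_hit)) fields[[ann_hit[1]]][-1] else character()
    muts <- row_ann[startsWith(row_ann, "mutation:")]
    muts <- sub("^mutation:", "", muts)
    muts <- muts[!(toupper(muts) %in% c("", "WT"))]
    label <- if (!length(muts)) "WT" else tryCatch(
      mutant_label(parse_mutant_label(paste(muts, collapse = "-"))),
      error = function(e) paste(muts, collapse = "-"))  # free-form labels
    modifier <- .annotation_value(row_ann, "modifier")
    if (is.null(modifier)) modifier <- global_modifier
    err_hit <- keyed(paste0("REACTIVITY_ERROR:", id))
    errors <- NULL
    if (length(err_hit)) {
      errors <- suppressWarnings(as.numeric(fields[[err_hit[1]]][-1]))
      if (length(errors) != length(seqpos) || anyNA(errors))
        stop("RDAT parse error at line ", err_hit[1],
             ": REACTIVITY_ERROR:", id, " length mismatch")
    }
    profiles[[length(profiles) + 1L]] <- reactivity_profile(
      values = vals, positions = seqpos, construct_ref = name,
      mutant_label = label, modifier = modifier, errors = errors)
  }
  if (!length(profiles)) stop("RDAT parse error: no REACTIVITY rows in ", path)

  construct <- rna_construct(name = name, sequence = sequence,
                             numbering_offset = offset)
  out <- rdat(name = name, construct = construct, profiles = profiles,
              structure = if (is.null(structure_str)) NULL else structure_str[1],
              annotations = annotations, comments = comments)
  message("read_rdat: ", length(profiles), " profiles from ", path)
  out
}

.annotation_value <- function(annotations, key) {
  hit <- annotations[startsWith(annotations, paste0(key, ":"))]
  if (!length(hit)) return(NULL)
  sub(paste0("^", key, ":"), "", hit[1])
}

#' Write an RDAT dataset to file
#'
#' Emits the tab-delimited RDAT block format.  Reactivity values are
#' written with 17 significant digits so a write/read round trip
#' reproduces them bit-exactly.
#'
#' @param x an [rdat()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rdat <- function(x, path) {
  stopifnot(inherits(x, "rdat"))
  con <- x$construct
  num <- function(v) sprintf("%.17g", v)
  seqpos <- x$profiles[[1]]$positions
  for (p in x$profiles)
    if (!identical(p$positions, seqpos))
      stop("all profiles must share one SEQPOS to be written to one RDAT")
  ch <- strsplit(con$sequence, "")[[1]]
  seqpos_lab <- paste0(ch[seqpos - con$numbering_offset], seqpos)
  out <- c(
    paste0("RDAT_VERSION\t0.34"),
    paste0("NAME\t", x$name),
    paste0("SEQUENCE\t", con$sequence),
    paste0("STRUCTURE\t", x$structure),
    paste0("OFFSET\t", con$numbering_offset),
    paste("SEQPOS", paste(seqpos_lab, collapse = "\t"), sep = "\t"))
  if (length(x$annotations))
    out <- c(out, paste("ANNOTATION", paste(x$annotations, collapse = "\t"),
                        sep = "\t"))
  for (k in seq_along(x$profiles)) {
    p <- x$profiles[[k]]
    ann <- character()
    if (p$mutant_label == "WT") {
      ann <- "mutation:WT"
    } else {
      subs <- strsplit(p$mutant_label, "-", fixed = TRUE)[[1]]
      ann <- paste0("mutation:", subs)
    }
    ann <- c(ann, paste0("modifier:", p$modifier))
    out <- c(out,
             paste(c(paste0("ANNOTATION_DATA:", k), ann), collapse = "\t"),
             paste(c(paste0("REACTIVITY:", k), num(p$values)), collapse = "\t"))
    if (!is.null(p$errors))
      out <- c(out, paste(c(paste0("REACTIVITY_ERROR:", k), num(p$errors)),
                          collapse = "\t"))
  }
  if (length(x$comments))
    out <- c(out, paste0("COMMENT\t", x$comments))
  writeLines(out, path)
  invisible(path)
}
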