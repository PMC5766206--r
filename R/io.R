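# Readers and writers: FASTA, Vienna dot-bracket, network YAML, TSV reports,
# run manifests.  All round-trips are lossless on the data model; windows
# are serialized as 0-based half-open integer pairs.

#' Read RNA sequences from FASTA
#'
#' @param path FASTA file.
#' @param transliterate Convert `T`/lowercase input to uppercase RNA
#'   (default); with `FALSE`, `T` is rejected.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path, transliterate = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  tibble::tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = vapply(as.character(ss), validate_rna, "",
                 transliterate = transliterate, USE.NAMES = FALSE))
}

#' Write RNA sequences to FASTA
#'
#' @param x Named character vector/list of sequences, or a data frame with
#'   `id` and `seq` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  ss <- Biostrings::BStringSet(unlist(x))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read Vienna-format sequence/structure records
#'
#' Records are an optional `>id` line, a sequence line, and a structure line
#' with an optional trailing energy in parentheses.
#'
#' @param path Input file.
#' @return Tibble with columns `id`, `seq`, `structure`, `energy`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    id <- NA_character_
    if (startsWith(lines[i], ">")) {
      id <- sub("^>\\s*", "", lines[i])
      i <- i + 1L
    }
    if (i + 1L > length(lines)) {
      abort("truncated Vienna record", class = "ribochain_parse_error")
    }
    sq <- gsub("&", "", lines[i], fixed = TRUE)
    st_line <- trimws(lines[i + 1L])
    m <- regmatches(st_line, regexec("^([().&x.]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?$",
                                     st_line))[[1]]
    if (length(m) == 0) {
      abort(sprintf("malformed structure line %d", i + 1L),
            class = "ribochain_parse_error")
    }
    st <- m[2]
    pd <- parse_dotbracket(st)  # validates balance, reports column
    if (pd$length != nchar(sq)) {
      abort(sprintf("structure length differs from sequence at line %d", i + 1L),
            class = "ribochain_parse_error")
    }
    k <- k + 1L
    rows[[k]] <- tibble::tibble(
      id = if (is.na(id)) paste0("record", k) else id,
      seq = validate_rna(sq, transliterate = TRUE),
      structure = st,
      energy = if (m[4] == "") NA_real_ else as.numeric(m[4]))
    i <- i + 2L
  }
  dplyr::bind_rows(rows)
}

#' Write Vienna-format records
#'
#' @param x A `fold_result`, or a data frame with `id`, `seq`, `structure`
#'   and optionally `energy`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(x, path) {
  if (inherits(x, "fold_result")) {
    x <- tibble::tibble(id = "fold", seq = insert_cuts_seq(x),
                        structure = x$structure, energy = x$energy)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[r]), con)
    writeLines(x$seq[r], con)
    e <- if ("energy" %in% names(x) && !is.na(x$energy[r])) {
      sprintf(" (%s)", format(x$energy[r], digits = 6))
    } else ""
    writeLines(paste0(x$structure[r], e), con)
  }
  invisible(path)
}

insert_cuts_seq <- function(fr) {
  chars <- strsplit(fr$sequence, "")[[1]]
  for (c in rev(sort(fr$cuts))) {
    if (c > 0 && c < length(chars)) chars <- append(chars, "&", after = c)
  }
  paste(chars, collapse = "")
}

#' Serialize a network specification to YAML
#'
#' @param net A `network_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(net, path) {
  doc <- list(
    schema_version = net$schema_version,
    species = lapply(seq_len(nrow(net$species)), function(i) {
      row <- net$species[i, ]
      list(id = row$id, role = row$role,
           seq = if (is.na(row$seq)) NULL else row$seq,
           length = row$length,
           fixed = lapply(row$fixed[[1]], function(fx)
             list(window = as.integer(fx$window), seq = fx$seq)),
           mutable = as.logical(row$mutable[[1]]))
    }),
    interactions = lapply(seq_len(nrow(net$interactions)), function(i) {
      row <- net$interactions[i, ]
      list(upstream = row$upstream, downstream = row$downstream,
           desired = row$desired,
           up_window = as.integer(row$up_window[[1]]),
           down_window = as.integer(row$down_window[[1]]),
           up_strand = if (is.na(row$up_strand)) NULL else row$up_strand)
    }),
    rbs_window = net$rbs_window,
    start_codon_window = net$start_codon_window,
    subobjectives = net$subobjectives,
    objective = unclass(net$weights),
    schedule = unclass(net$schedule),
    seed = net$seed)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a network specification from YAML
#'
#' @param path YAML file written by [write_network_yaml()] (schema
#'   version 1).
#' @return A `network_spec`.
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    abort(sprintf("unknown network schema version: %s",
                  doc$schema_version %||% "<missing>"),
          class = "ribochain_parse_error")
  }
  species <- dplyr::bind_rows(lapply(doc$species, function(s) {
    tibble::tibble(id = s$id, role = s$role,
                   seq = s$seq %||% NA_character_,
                   length = as.integer(s$length),
                   fixed = list(lapply(s$fixed, function(fx)
                     list(window = as.integer(fx$window), seq = fx$seq))),
                   mutable = list(as.logical(s$mutable)))
  }))
  interactions <- dplyr::bind_rows(lapply(doc$interactions, function(it) {
    tibble::tibble(upstream = it$upstream, downstream = it$downstream,
                   desired = it$desired,
                   up_window = list(as.integer(it$up_window)),
                   down_window = list(as.integer(it$down_window)),
                   up_strand = it$up_strand %||% NA_character_)
  }))
  w <- doc$objective %||% list()
  weights <- do.call(objective_weights, w[names(w) %in%
    names(formals(objective_weights))])
  s <- doc$schedule %||% list()
  schedule <- do.call(anneal_schedule, s[names(s) %in%
    names(formals(anneal_schedule))])
  net <- network_spec(species, interactions,
                      rbs_window = doc$rbs_window,
                      start_codon_window = doc$start_codon_window,
                      subobjectives = doc$subobjectives,
                      weights = weights, schedule = schedule)
  net$seed <- doc$seed
  net
}

#' Write a report table as TSV
#'
#' Numeric columns are serialized with 6 significant digits; a header
#' comment names the units of the energy columns.
#'
#' @param df Data frame.
#' @param path Output file.
#' @param units Optional named character vector mapping column names to
#'   units, emitted as `#` header comments.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, units = NULL) {
  df <- as.data.frame(df)
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- signif(df[[cn]], 6)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) {
    for (cn in names(units)) {
      writeLines(sprintf("# %s: %s", cn, units[[cn]]), con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run manifest for provenance
#'
#' Every CLI run records its command, seed, backend identity and parameter
#' digest, timestamps, and output files as a JSON sidecar.
#'
#' @param command Command name.
#' @param seed Integer seed or `NA`.
#' @param model Energy model in effect.
#' @param outputs Character vector of output paths.
#' @param config Optional named list of extra configuration.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(command, seed, model, outputs, config = list()) {
  structure(
    list(command = command, seed = seed, backend_id = backend_id(model),
         activation_model = "toehold-opening-sum",
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = outputs, config = config),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
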