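#' Default task battery
#'
#' The standard session layout: a rest measurement, nine cognitive tasks
#' (0-back, 2-back, Sternberg, serial Sternberg, Stroop, switch-PAR,
#' switch-NUM, switch-XXX, AOSPAN) and a closing rest, with the canonical
#' durations (minutes: 3, 5, 5, 10, 10, 5, 5, 5, 10, 20, 3 — 81 min total).
#'
#' @param scale divide all durations by this factor (e.g. `scale = 5` for a
#'   desk-scale run). Scaled durations are floored at `min_block_s` so that
#'   baseline extraction (first minute of each block) stays possible.
#' @param min_block_s minimum block duration in seconds after scaling.
#' @return data frame with columns `task_id`, `start_s`, `end_s`.
#' @export
default_battery <- function(scale = 1, min_block_s = 60) {
  tasks <- c("rest_start", "0-back", "2-back", "sternberg", "ser_sternberg",
             "stroop", "switch-PAR", "switch-NUM", "switch-XXX", "AOSPAN",
             "rest_end")
  mins <- c(3, 5, 5, 10, 10, 5, 5, 5, 10, 20, 3)
  dur <- pmax(mins * 60 / scale, if (scale > 1) min_block_s else 0)
  end <- cumsum(dur)
  data.frame(task_id = tasks, start_s = c(0, end[-length(end)]), end_s = end,
             stringsAsFactors = FALSE)
}

#' Read a session manifest
#'
#' A manifest maps recordings to subjects and task blocks. YAML or JSON, a
#' list of entries with fields `subject`, `path`, and `blocks`, each block
#' having `task`, `start_s`, `end_s` (or `start_min`/`end_min`, converted to
#' seconds). Blocks must be non-overlapping and forward-running.
#'
#' @param path manifest file (`.yaml`/`.yml`/`.json`).
#' @return list of entries, each a list with `subject`, `path` and a block
#'   data frame (`task_id`, `start_s`, `end_s`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = FALSE),
                stop("unsupported manifest format: .", ext))
  if (is.null(doc) || length(doc) == 0L) return(list())
  lapply(doc, function(entry) {
    blocks <- do.call(rbind, lapply(entry$blocks, function(b) {
      if (!is.null(b$start_min)) {
        b$start_s <- b$start_min * 60
        b$end_s <- b$end_min * 60
      }
      data.frame(task_id = as.character(b$task),
                 start_s = as.numeric(b$start_s),
                 end_s = as.numeric(b$end_s), stringsAsFactors = FALSE)
    }))
    list(subject = as.character(entry$subject),
         path = as.character(entry$path %||% NA_character_),
         blocks = validate_blocks(blocks))
  })
}

#' Write a session manifest
#'
#' @param entries list as returned by [read_manifest()].
#' @param path output `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  doc <- lapply(entries, function(e) {
    list(subject = e$subject, path = e$path,
         blocks = lapply(seq_len(nrow(e$blocks)), function(i) {
           list(task = e$blocks$task_id[i],
                start_s = e$blocks$start_s[i],
                end_s = e$blocks$end_s[i])
         }))
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(doc, path)
  else if (ext == "json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported manifest format: .", ext)
  invisible(path)
}
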