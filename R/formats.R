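#' Read a snapshot clustering table
#'
#' The clustering of the receptor ensemble is consumed as a plain table with
#' one row per snapshot: `snapshot_id`, `cluster_id`, and an optional free-text
#' `similarity_label` describing the similarity function that produced the
#' cluster. Row order within a cluster is preserved; it fixes the order in
#' which subgroups are later formed.
#'
#' @param path Path to a CSV file, or a data frame already in memory.
#' @return A tibble with columns `snapshot_id`, `cluster_id`,
#'   `similarity_label` (NA when absent), ordered as read.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("snapshot_id,cluster_id", "s1,c1", "s2,c1", "s3,c2"), f)
#' read_clustering(f)
#' @export
read_clustering <- function(path) {
  tbl <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  missing_cols <- setdiff(c("snapshot_id", "cluster_id"), names(tbl))
  if (length(missing_cols)) {
    abort(paste0(
      "Clustering table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tbl <- tbl |>
    mutate(
      snapshot_id = as.character(.data$snapshot_id),
      cluster_id = as.character(.data$cluster_id)
    )
  if (!"similarity_label" %in% names(tbl)) {
    tbl$similarity_label <- NA_character_
  }
  dup <- unique(tbl$snapshot_id[duplicated(tbl$snapshot_id)])
  if (length(dup)) {
    abort(paste0(
      "Duplicate snapshot id(s) in clustering: ",
      paste(dup, collapse = ", ")
    ))
  }
  tbl |> select("snapshot_id", "cluster_id", "similarity_label")
}

#' Write / read the campaign control file
#'
#' The control file is the XML contract between the analysis side (which owns
#' subgroup status and priority) and the dispatch side (which tracks docked
#' snapshots). Its root `experiment` element carries the experiment id;
#' each nested `subgroup` element carries `id`, `stat`, and `priority`
#' attributes and one `snapshot` child per member with a `docked` flag.
#'
#' @param experiment_id Integer experiment identifier.
#' @param subgroups Tibble with columns `subgroup_id`, `status`, `priority`.
#' @param snapshots Tibble with columns `snapshot_id`, `subgroup_id`, `docked`.
#' @param path Optional file path; when given the document is also written there.
#' @return For `write_control_file`, an `xml2::xml_document` (invisibly when
#'   `path` is given). For `read_control_file`, a list of class `rffr_control`
#'   with `experiment_id`, `subgroups`, and `snapshots` tibbles.
#' @examples
#' subs <- tibble::tibble(subgroup_id = "G1L1", status = "A", priority = 2L)
#' snaps <- tibble::tibble(snapshot_id = c("s1", "s2"),
#'                         subgroup_id = "G1L1", docked = c(TRUE, FALSE))
#' doc <- write_control_file(7L, subs, snaps)
#' read_control_file(doc)$experiment_id
#' @export
write_control_file <- function(experiment_id, subgroups, snapshots, path = NULL) {
  stopifnot(
    all(c("subgroup_id", "status", "priority") %in% names(subgroups)),
    all(c("snapshot_id", "subgroup_id", "docked") %in% names(snapshots))
  )
  if (!all(subgroups$status %in% subgroup_statuses)) {
    abort("Unknown subgroup status letter; expected A, F, D, or P.")
  }
  doc <- xml2::xml_new_root("experiment", id = as.character(as.integer(experiment_id)))
  for (i in seq_len(nrow(subgroups))) {
    sg <- xml2::xml_add_child(
      doc, "subgroup",
      id = subgroups$subgroup_id[i],
      stat = subgroups$status[i],
      priority = as.character(subgroups$priority[i])
    )
    members <- snapshots[snapshots$subgroup_id == subgroups$subgroup_id[i], ]
    for (j in seq_len(nrow(members))) {
      xml2::xml_add_child(
        sg, "snapshot",
        id = members$snapshot_id[j],
        docked = ifelse(members$docked[j], "true", "false")
      )
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' @param x An `xml2::xml_document`, an XML string, or a file path.
#' @rdname write_control_file
#' @export
read_control_file <- function(x) {
  doc <- as_xml_doc(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "experiment") {
    abort("Control file root element must be <experiment>.")
  }
  experiment_id <- as.integer(xml2::xml_attr(root, "id"))
  if (is.na(experiment_id)) abort("Control file lacks a numeric experiment id.")
  sg_nodes <- xml2::xml_find_all(root, "./subgroup")
  subgroups <- tibble(
    subgroup_id = xml2::xml_attr(sg_nodes, "id"),
    status = xml2::xml_attr(sg_nodes, "stat"),
    priority = as.integer(xml2::xml_attr(sg_nodes, "priority"))
  )
  if (nrow(subgroups) && !all(subgroups$status %in% subgroup_statuses)) {
    bad <- setdiff(unique(subgroups$status), subgroup_statuses)
    abort(paste0("Unknown subgroup status letter: ", paste(bad, collapse = ", ")))
  }
  if (nrow(subgroups) && any(!subgroups$priority %in% 1:3)) {
    abort("Subgroup priority outside 1..3 in control file.")
  }
  snap_rows <- purrr::map(sg_nodes, function(sg) {
    sn <- xml2::xml_find_all(sg, "./snapshot")
    tibble(
      snapshot_id = xml2::xml_attr(sn, "id"),
      subgroup_id = xml2::xml_attr(sg, "id"),
      docked = xml2::xml_attr(sn, "docked") == "true"
    )
  })
  snapshots <- if (length(snap_rows)) {
    bind_rows(snap_rows)
  } else {
    tibble(snapshot_id = character(), subgroup_id = character(), docked = logical())
  }
  structure(
    list(experiment_id = experiment_id, subgroups = subgroups, snapshots = snapshots),
    class = "rffr_control"
  )
}

#' Write / read a subgroup update file
#'
#' An update file records exactly one change to one subgroup: either a new
#' priority (1-3) or a new status (`A`, `F`, or `D`). One file is emitted each
#' time the adaptive analysis modifies a subgroup, keeping the dispatch side in
#' step with the analysis side.
#'
#' @param subgroup_id Subgroup identifier, e.g. `"G1L1"`.
#' @param priority New priority, or `NULL`.
#' @param status New status, or `NULL`. Exactly one of `priority`/`status`
#'   must be given.
#' @param path Optional file path to write to.
#' @return For `write_update_file`, an `xml2::xml_document`. For
#'   `read_update_file`, a list of class `rffr_update` with `subgroup_id` and
#'   one of `priority` or `status` set (the other `NULL`).
#' @examples
#' up <- write_update_file("G1L1", priority = 1)
#' read_update_file(up)
#' @export
write_update_file <- function(subgroup_id, priority = NULL, status = NULL,
                              path = NULL) {
  if (is.null(priority) == is.null(status)) {
    abort("An update records exactly one change: give `priority` or `status`.")
  }
  if (!is.null(priority)) {
    priority <- as.integer(priority)
    if (!priority %in% 1:3) abort("Update priority must be 1, 2, or 3.")
    doc <- xml2::xml_new_root("update",
      subgroup = subgroup_id,
      priority = as.character(priority)
    )
  } else {
    if (!status %in% c("A", "F", "D")) {
      abort("Update status must be A, F, or D.")
    }
    doc <- xml2::xml_new_root("update", subgroup = subgroup_id, stat = status)
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' @rdname write_update_file
#' @export
read_update_file <- function(x) {
  doc <- as_xml_doc(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "update") {
    abort("Update file root element must be <update>.")
  }
  subgroup_id <- xml2::xml_attr(root, "subgroup")
  if (is.na(subgroup_id)) abort("Update file lacks a subgroup id.")
  pr <- xml2::xml_attr(root, "priority")
  st <- xml2::xml_attr(root, "stat")
  if (is.na(pr) == is.na(st)) {
    abort("Update file must carry exactly one of `priority` or `stat`.")
  }
  if (!is.na(pr)) {
    priority <- as.integer(pr)
    if (!priority %in% 1:3) abort("Update priority must be 1, 2, or 3.")
    out <- list(subgroup_id = subgroup_id, priority = priority, status = NULL)
  } else {
    if (!st %in% c("A", "F", "D")) abort("Update status must be A, F, or D.")
    out <- list(subgroup_id = subgroup_id, priority = NULL, status = st)
  }
  structure(out, class = "rffr_update")
}

as_xml_doc <- function(x) {
  if (inherits(x, "xml_document")) {
    x
  } else if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE)) {
    xml2::read_xml(x) # path
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
}

provenance_kinds <- c("dispatch", "result", "analysis", "change", "queue_built")

#' Append one record to a provenance log
#'
#' Provenance is a JSON-lines file ordered by an integer ordinal instead of
#' wall-clock timestamps, so a rerun with the same seed reproduces the log
#' byte for byte.
#'
#' @param record List with `ordinal` (integer), `kind` (one of dispatch,
#'   result, analysis, change, queue_built), and `payload` (named list).
#' @param path Log file path; created on first append.
#' @return The record, invisibly.
#' @examples
#' log <- tempfile(fileext = ".jsonl")
#' append_provenance(list(ordinal = 1, kind = "dispatch",
#'                        payload = list(batch = 1)), log)
#' read_provenance(log)
#' @export
append_provenance <- function(record, path) {
  stopifnot(is.list(record), !is.null(record$ordinal), !is.null(record$kind))
  if (!record$kind %in% provenance_kinds) {
    abort(paste0("Unknown provenance event kind: ", record$kind))
  }
  ordinal <- as.integer(record$ordinal)
  if (file.exists(path) && file.size(path) > 0L) {
    last <- tail(readLines(path, warn = FALSE), 1L)
    last_ord <- jsonlite::fromJSON(last)$ordinal
    if (ordinal <= last_ord) {
      abort(sprintf(
        "Provenance ordinals must strictly increase (last %d, got %d).",
        last_ord, ordinal
      ))
    }
  }
  line <- jsonlite::toJSON(
    list(ordinal = ordinal, kind = record$kind, payload = record$payload),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(record)
}

#' @param path Log file path.
#' @rdname append_provenance
#' @export
read_provenance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  purrr::map(lines, \(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
}

# bulk writer used by the campaign loop (records already ordinal-ordered)
write_provenance <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(
      list(ordinal = as.integer(r$ordinal), kind = r$kind, payload = r$payload),
      auto_unbox = TRUE, null = "null", digits = NA
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extract the best free energy of binding from AutoDock DLG text
#'
#' Scans the docking log of an AutoDock 4.2 run for its reported
#' "Estimated Free Energy of Binding" lines (one per LGA run) and returns the
#' minimum, i.e. the best FEB across runs, in kcal/mol.
#'
#' @param x A file path or a character vector of DLG lines.
#' @return A single numeric, the best (most negative) FEB found.
#' @examples
#' lines <- c(
#'   "DOCKED: USER    Estimated Free Energy of Binding    =   -7.20 kcal/mol",
#'   "DOCKED: USER    Estimated Free Energy of Binding    =   -8.10 kcal/mol"
#' )
#' parse_dlg_best_feb(lines)
#' @export
parse_dlg_best_feb <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  hits <- grep("Estimated Free Energy of Binding", lines, value = TRUE)
  if (!length(hits)) {
    abort("No 'Estimated Free Energy of Binding' line found in DLG text.")
  }
  vals <- as.numeric(sub(
    ".*Estimated Free Energy of Binding\\s*=\\s*([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?).*",
    "\\1", hits
  ))
  if (anyNA(vals)) abort("Could not parse an energy value from a DLG line.")
  min(vals)
}
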