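## Event-record data model: animals, dose events, observations.
## The on-disk format is a NONMEM-style CSV (one row per dose or observation).

.endpoints <- c("plasma_conc", "brain_conc_total",
                "sol_ab40", "insol_ab40", "sol_ab42", "insol_ab42")
.dvid_map <- stats::setNames(seq_along(.endpoints), .endpoints)
.routes <- c("oral", "sc", "iv")
.strains <- c("C57BL/6", "Tg2576", "littermate")
.arms <- c("vehicle", "treated", "naive")

.normalize_route <- function(x) {
  x <- tolower(gsub("[. ]", "", as.character(x)))
  out <- c(po = "oral", oral = "oral", sc = "sc", iv = "iv")[x]
  if (any(is.na(out) & !is.na(x))) {
    stop("unknown route value(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Assemble an event-record dataset
#'
#' Bundles animal covariates, dosing events and observations into a validated
#' dataset object, the common currency of all fitting, simulation and
#' diagnostic functions in the package.
#'
#' @param animals Data frame with columns `animal_id`, `strain` (one of
#'   `"C57BL/6"`, `"Tg2576"`, `"littermate"`), `age_at_start_months`,
#'   `study_id`, `arm` (one of `"vehicle"`, `"treated"`, `"naive"`).
#' @param doses Data frame with columns `animal_id`, `time_h` (hours since
#'   study start), `amount` (umol/kg, positive), `route` (`"oral"`, `"sc"`,
#'   `"iv"`), `vehicle` (1, 2 or 3; only meaningful for oral dosing).  May be
#'   `NULL` or empty for undosed datasets.
#' @param observations Data frame with columns `animal_id`, `time_h`,
#'   `endpoint` (one of the six supported endpoints), `value` (umol/L for drug
#'   concentrations, pg/mg for amyloid-beta), `blq_flag` (logical), `lloq`
#'   (same units as `value`, `NA` if not determined).
#' @return An object of class `"abeta_dataset"`: a list with elements
#'   `animals`, `doses` and `observations`, each a validated, time-ordered
#'   data frame.
#' @seealso [read_dataset()], [write_dataset()], [exclude_blq()]
#' @export
as_dataset <- function(animals, doses = NULL, observations = NULL) {
  animals <- as.data.frame(animals)
  need <- c("animal_id", "strain", "age_at_start_months", "study_id", "arm")
  miss <- setdiff(need, names(animals))
  if (length(miss)) stop("animals is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(animals$animal_id)) {
    stop("duplicated animal_id in animals", call. = FALSE)
  }
  if (!all(animals$strain %in% .strains)) stop("unknown strain", call. = FALSE)
  if (!all(animals$arm %in% .arms)) stop("unknown arm", call. = FALSE)
  if (any(!is.finite(animals$age_at_start_months)) ||
      any(animals$age_at_start_months <= 0)) {
    stop("age_at_start_months must be positive", call. = FALSE)
  }

  if (is.null(doses) || !nrow(as.data.frame(doses))) {
    doses <- data.frame(animal_id = character(), time_h = numeric(),
                        amount = numeric(), route = character(),
                        vehicle = integer())
  } else {
    doses <- as.data.frame(doses)
    need <- c("animal_id", "time_h", "amount", "route", "vehicle")
    miss <- setdiff(need, names(doses))
    if (length(miss)) stop("doses is missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    doses$route <- .normalize_route(doses$route)
    if (any(doses$amount <= 0) || any(!is.finite(doses$amount))) {
      stop("dose amounts must be positive", call. = FALSE)
    }
    if (any(doses$time_h < 0)) stop("dose times must be >= 0", call. = FALSE)
    if (!all(doses$animal_id %in% animals$animal_id)) {
      stop("doses reference unknown animal_id", call. = FALSE)
    }
    doses <- doses[order(match(doses$animal_id, animals$animal_id),
                         doses$time_h), , drop = FALSE]
  }

  if (is.null(observations) || !nrow(as.data.frame(observations))) {
    observations <- data.frame(animal_id = character(), time_h = numeric(),
                               endpoint = character(), value = numeric(),
                               blq_flag = logical(), lloq = numeric())
  } else {
    observations <- as.data.frame(observations)
    need <- c("animal_id", "time_h", "endpoint", "value")
    miss <- setdiff(need, names(observations))
    if (length(miss)) stop("observations is missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (is.null(observations$blq_flag)) observations$blq_flag <- FALSE
    if (is.null(observations$lloq)) observations$lloq <- NA_real_
    if (!all(observations$endpoint %in% .endpoints)) {
      stop("unknown endpoint(s): ",
           paste(setdiff(unique(observations$endpoint), .endpoints),
                 collapse = ", "), call. = FALSE)
    }
    bad <- !observations$blq_flag &
      (!is.finite(observations$value) | observations$value < 0)
    if (any(bad)) stop("observation values must be >= 0 unless flagged BLQ",
                       call. = FALSE)
    if (!all(observations$animal_id %in% animals$animal_id)) {
      stop("observations reference unknown animal_id", call. = FALSE)
    }
    observations <- observations[order(match(observations$animal_id,
                                             animals$animal_id),
                                       observations$time_h), , drop = FALSE]
  }

  rownames(animals) <- rownames(doses) <- rownames(observations) <- NULL
  structure(list(animals = animals, doses = doses, observations = observations),
            class = "abeta_dataset")
}

#' @export
print.abeta_dataset <- function(x, ...) {
  cat("Event-record dataset:", nrow(x$animals), "animals,",
      nrow(x$doses), "dose events,", nrow(x$observations), "observations\n")
  if (nrow(x$animals)) {
    cat("  studies:", paste(unique(x$animals$study_id), collapse = ", "), "\n")
    cat("  arms:   ", paste(names(table(x$animals$arm)),
                            table(x$animals$arm), sep = ":", collapse = "  "), "\n")
  }
  if (nrow(x$observations)) {
    cat("  endpoints:", paste(names(table(x$observations$endpoint)),
                              table(x$observations$endpoint),
                              sep = ":", collapse = "  "), "\n")
    nblq <- sum(x$observations$blq_flag)
    if (nblq) cat("  below-LLOQ observations:", nblq, "\n")
  }
  invisible(x)
}

#' Read an event-record dataset from CSV
#'
#' Reads a NONMEM-style event-record table.  Required columns are `ID`,
#' `TIME`, `DV`, `AMT`, `EVID`, `DVID`, `AGE`, `ROUTE`, `VEHICLE`, `STUDY`,
#' `ARM`, `LLOQ`; a `STRAIN` column is used when present (defaulting to
#' Tg2576 otherwise).  Rows with `EVID = 1` become dose events, rows with
#' `EVID = 0` observations.  Missing values are coded as `"."`.  `DVID` maps
#' 1:6 onto plasma drug concentration, total brain drug concentration, and
#' soluble/insoluble Abeta40 and Abeta42.  An observation whose `DV` falls
#' below its `LLOQ` is flagged as below the limit of quantification.
#'
#' @param path Path to a CSV file.
#' @return An [as_dataset()] object.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, na.strings = c(".", "", "NA"),
                         stringsAsFactors = FALSE)
  need <- c("ID", "TIME", "DV", "AMT", "EVID", "DVID", "AGE",
            "ROUTE", "VEHICLE", "STUDY", "ARM", "LLOQ")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("dataset file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(raw)) stop("dataset file has no records", call. = FALSE)
  raw$ID <- as.character(raw$ID)

  first <- raw[!duplicated(raw$ID), , drop = FALSE]
  animals <- data.frame(
    animal_id = first$ID,
    strain = if ("STRAIN" %in% names(raw)) as.character(first$STRAIN) else "Tg2576",
    age_at_start_months = as.numeric(first$AGE),
    study_id = as.character(first$STUDY),
    arm = as.character(first$ARM)
  )

  drows <- raw[raw$EVID == 1, , drop = FALSE]
  doses <- NULL
  if (nrow(drows)) {
    if (any(!is.finite(as.numeric(drows$AMT)) | as.numeric(drows$AMT) <= 0)) {
      stop("dose rows (EVID=1) must carry a positive AMT", call. = FALSE)
    }
    doses <- data.frame(
      animal_id = drows$ID,
      time_h = as.numeric(drows$TIME),
      amount = as.numeric(drows$AMT),
      route = .normalize_route(drows$ROUTE),
      vehicle = ifelse(is.na(drows$VEHICLE), 1L, as.integer(drows$VEHICLE))
    )
  }

  orows <- raw[raw$EVID == 0, , drop = FALSE]
  observations <- NULL
  if (nrow(orows)) {
    dvid <- as.integer(orows$DVID)
    if (any(is.na(dvid)) || any(!dvid %in% seq_along(.endpoints))) {
      stop("unknown DVID in observation rows", call. = FALSE)
    }
    lloq <- as.numeric(orows$LLOQ)
    dv <- as.numeric(orows$DV)
    observations <- data.frame(
      animal_id = orows$ID,
      time_h = as.numeric(orows$TIME),
      endpoint = .endpoints[dvid],
      value = dv,
      blq_flag = !is.na(lloq) & !is.na(dv) & dv < lloq,
      lloq = lloq
    )
  }
  as_dataset(animals, doses, observations)
}

#' Write an event-record dataset to CSV
#'
#' Inverse of [read_dataset()]; the round trip is lossless for all fields.
#'
#' @param ds An [as_dataset()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "abeta_dataset"))
  an <- ds$animals
  cov_of <- function(id) an[match(id, an$animal_id), , drop = FALSE]

  rows <- list()
  if (nrow(ds$doses)) {
    cv <- cov_of(ds$doses$animal_id)
    rows$dose <- data.frame(
      ID = ds$doses$animal_id, TIME = ds$doses$time_h, DV = NA_real_,
      AMT = ds$doses$amount, EVID = 1L, DVID = NA_integer_,
      AGE = cv$age_at_start_months, ROUTE = ds$doses$route,
      VEHICLE = ds$doses$vehicle, STUDY = cv$study_id, ARM = cv$arm,
      LLOQ = NA_real_, STRAIN = cv$strain
    )
  }
  if (nrow(ds$observations)) {
    cv <- cov_of(ds$observations$animal_id)
    rows$obs <- data.frame(
      ID = ds$observations$animal_id, TIME = ds$observations$time_h,
      DV = ds$observations$value, AMT = NA_real_, EVID = 0L,
      DVID = unname(.dvid_map[ds$observations$endpoint]),
      AGE = cv$age_at_start_months, ROUTE = NA_character_,
      VEHICLE = NA_integer_, STUDY = cv$study_id, ARM = cv$arm,
      LLOQ = ds$observations$lloq, STRAIN = cv$strain
    )
  }
  out <- do.call(rbind, rows)
  # keep animals without records representable? all animals must have >= 1 row
  missing_animals <- setdiff(an$animal_id, out$ID)
  if (length(missing_animals)) {
    cv <- cov_of(missing_animals)
    out <- rbind(out, data.frame(
      ID = missing_animals, TIME = 0, DV = NA_real_, AMT = NA_real_,
      EVID = 2L, DVID = NA_integer_, AGE = cv$age_at_start_months,
      ROUTE = NA_character_, VEHICLE = NA_integer_, STUDY = cv$study_id,
      ARM = cv$arm, LLOQ = NA_real_, STRAIN = cv$strain
    ))
  }
  out <- out[order(match(out$ID, an$animal_id), out$TIME, -out$EVID), ,
             drop = FALSE]
  utils::write.csv(.na_to_dot(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.na_to_dot <- function(df) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    df[[j]] <- v
  }
  df
}

#' Exclude below-LLOQ observations
#'
#' Removes observations flagged as below the lower limit of quantification
#' for the named endpoints (the M1 approach: exclusion, no likelihood-based
#' imputation) and reports the excluded fraction per endpoint.
#'
#' @param ds An [as_dataset()] object.
#' @param endpoints Character vector of endpoints to filter; defaults to all.
#' @return A list with elements `dataset` (the filtered dataset) and `report`
#'   (a data frame with per-endpoint `n_total`, `n_excluded` and
#'   `fraction_excluded`).
#' @export
exclude_blq <- function(ds, endpoints = .endpoints) {
  stopifnot(inherits(ds, "abeta_dataset"))
  endpoints <- match.arg(endpoints, .endpoints, several.ok = TRUE)
  obs <- ds$observations
  drop <- obs$blq_flag & obs$endpoint %in% endpoints
  report <- do.call(rbind, lapply(endpoints, function(ep) {
    sel <- obs$endpoint == ep
    data.frame(endpoint = ep, n_total = sum(sel),
               n_excluded = sum(sel & drop),
               fraction_excluded = if (sum(sel)) sum(sel & drop) / sum(sel) else 0)
  }))
  out <- ds
  out$observations <- obs[!drop, , drop = FALSE]
  rownames(out$observations) <- NULL
  list(dataset = out, report = report)
}

#' Read a parameter configuration file
#'
#' Reads a YAML or JSON file of named parameter values (keys match the
#' published parameter symbols, e.g. `CL`, `V2`, `alpha`, `EC_i`, `Imax`,
#' `SL`) and returns it as a named list.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of parameter values.
#' @export
read_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
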