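#' Pump module command protocol
#'
#' Pump modules identify themselves when connected and then exchange a small
#' command vocabulary with the controller. The wire format is one
#' newline-terminated ASCII line per message: an upper-case verb followed by
#' `key=value` tokens, with values percent-encoded so free text survives the
#' trip. `protocol_decode(protocol_encode(m))` is the identity on the whole
#' message grammar.
#'
#' Message constructors return plain tagged lists:
#' \itemize{
#'   \item `list(type = "IDENTIFY")` — controller asks who is there
#'   \item `list(type = "IDENTITY", identity = <module_identity>)`
#'   \item `list(type = "DOSE", amount = <num>, unit = "ms"|"steps",
#'         rate = <num or NULL>)`
#'   \item `list(type = "STOP")`, `list(type = "GET_CAL")`,
#'         `list(type = "ACK")`
#'   \item `list(type = "SET_CAL", calibration = <pump spec>)`
#'   \item `list(type = "ERROR", text = <chr>)`
#' }
#'
#' @param msg a message list as above.
#' @return `protocol_encode`: a single newline-terminated line.
#'   `protocol_decode`: the message list.
#' @export
protocol_encode <- function(msg) {
  stopifnot(is.list(msg), is.character(msg$type))
  enc <- .pct_encode
  num <- function(x) sprintf("%.17g", x)
  body <- switch(msg$type,
    IDENTIFY = , STOP = , GET_CAL = , ACK = "",
    ERROR = paste0(" text=", enc(msg$text)),
    DOSE = {
      stopifnot(msg$unit %in% c("ms", "steps"), is.numeric(msg$amount))
      paste0(" amount=", num(msg$amount), " unit=", msg$unit,
             if (!is.null(msg$rate)) paste0(" rate=", num(msg$rate)))
    },
    SET_CAL = paste0(" ", .encode_spec(msg$calibration, enc, num)),
    IDENTITY = {
      id <- msg$identity
      stopifnot(inherits(id, "module_identity"))
      paste0(" name=", enc(id$name), " description=", enc(id$description),
             " reagent=", enc(id$reagent), " ",
             .encode_spec(id$calibration, enc, num))
    },
    stop("unknown message type: ", msg$type, call. = FALSE)
  )
  paste0(msg$type, body, "\n")
}

.SPEC_NUM_FIELDS <- list(
  syringe_pump_spec = c("steps_per_rev", "lead", "syringe_inner_diameter",
                        "syringe_capacity", "plunger_position",
                        "residual_ml", "dispensed_ml"),
  peristaltic_pump_spec = c("coefficient", "dead_time", "min_reliable_dose",
                            "dispensed_ml")
)

.encode_spec <- function(spec, enc, num) {
  cls <- class(spec)[1]
  fields <- .SPEC_NUM_FIELDS[[cls]]
  if (is.null(fields)) stop("not a pump specification", call. = FALSE)
  ptype <- if (cls == "syringe_pump_spec") "syringe" else "peristaltic"
  kv <- paste0(fields, "=", vapply(fields, function(f) num(spec[[f]]),
                                   character(1)))
  extra <- if (ptype == "peristaltic")
    paste0(" supply_voltage_tag=", enc(spec$supply_voltage_tag)) else ""
  paste0("pump_type=", ptype, " ", paste(kv, collapse = " "), extra)
}

.decode_spec <- function(kv) {
  ptype <- kv[["pump_type"]]
  if (is.null(ptype) || !ptype %in% c("syringe", "peristaltic"))
    stop("protocol error: missing or bad pump_type", call. = FALSE)
  cls <- if (ptype == "syringe") "syringe_pump_spec" else "peristaltic_pump_spec"
  fields <- .SPEC_NUM_FIELDS[[cls]]
  vals <- lapply(fields, function(f) {
    v <- kv[[f]]
    if (is.null(v)) stop("protocol error: missing field ", f, call. = FALSE)
    as.numeric(v)
  })
  names(vals) <- fields
  if (cls == "peristaltic_pump_spec")
    vals$supply_voltage_tag <- kv[["supply_voltage_tag"]]
  # reorder to constructor layout
  order <- if (cls == "syringe_pump_spec")
    c("steps_per_rev", "lead", "syringe_inner_diameter", "syringe_capacity",
      "plunger_position", "residual_ml", "dispensed_ml")
  else
    c("coefficient", "dead_time", "min_reliable_dose", "supply_voltage_tag",
      "dispensed_ml")
  structure(vals[order], class = cls)
}

#' @rdname protocol_encode
#' @param line one protocol line (trailing newline optional).
#' @export
protocol_decode <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  line <- sub("[\r\n]+$", "", line)
  if (!nzchar(line) || !grepl("^[A-Z_]+( |$)", line))
    stop("protocol error: malformed line: ", line, call. = FALSE)
  toks <- strsplit(line, " ", fixed = TRUE)[[1]]
  type <- toks[1]
  kv <- list()
  if (length(toks) > 1L) {
    body <- toks[-1]
    if (!all(grepl("^[A-Za-z_]+=", body)))
      stop("protocol error: malformed token in: ", line, call. = FALSE)
    keys <- sub("=.*$", "", body)
    vals <- vapply(sub("^[A-Za-z_]+=", "", body), .pct_decode,
                   character(1), USE.NAMES = FALSE)
    kv <- stats::setNames(as.list(vals), keys)
  }
  switch(type,
    IDENTIFY = , STOP = , GET_CAL = , ACK = list(type = type),
    ERROR = list(type = "ERROR", text = kv[["text"]] %||% ""),
    DOSE = {
      if (is.null(kv[["amount"]]) || is.null(kv[["unit"]]) ||
          !kv[["unit"]] %in% c("ms", "steps"))
        stop("protocol error: bad DOSE: ", line, call. = FALSE)
      list(type = "DOSE", amount = as.numeric(kv[["amount"]]),
           unit = kv[["unit"]],
           rate = if (!is.null(kv[["rate"]])) as.numeric(kv[["rate"]]))
    },
    SET_CAL = list(type = "SET_CAL", calibration = .decode_spec(kv)),
    IDENTITY = {
      for (f in c("name", "description", "reagent"))
        if (is.null(kv[[f]]))
          stop("protocol error: bad IDENTITY: ", line, call. = FALSE)
      cal <- .decode_spec(kv)
      list(type = "IDENTITY",
           identity = module_identity(kv[["name"]], kv[["description"]],
                                      kv[["reagent"]], cal))
    },
    stop("protocol error: unknown verb in: ", line, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Percent-encoding of arbitrary text into space-free ASCII tokens.
# (Done by hand: every byte outside [A-Za-z0-9._~-] becomes %XX.)
.pct_encode <- function(x) {
  bytes <- charToRaw(as.character(x))
  ok <- bytes %in% charToRaw(
    paste0("ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghijklmnopqrstuvwxyz",
           "0123456789._~-"))
  chars <- character(length(bytes))
  chars[ok] <- vapply(bytes[ok], rawToChar, character(1))
  chars[!ok] <- sprintf("%%%02X", as.integer(bytes[!ok]))
  paste(chars, collapse = "")
}

.pct_decode <- function(x) {
  bytes <- charToRaw(x)
  out <- raw(0)
  i <- 1L
  while (i <= length(bytes)) {
    if (bytes[i] == charToRaw("%")) {
      if (i + 2L > length(bytes))
        stop("protocol error: truncated percent escape", call. = FALSE)
      out <- c(out, as.raw(strtoi(rawToChar(bytes[(i + 1L):(i + 2L)]), 16L)))
      i <- i + 3L
    } else {
      out <- c(out, bytes[i])
      i <- i + 1L
    }
  }
  rawToChar(out)
}

#' In-memory transport pair
#'
#' The transport contract is two functions, `write_line(line)` and
#' `read_line()` (returning `NULL` when nothing is pending). This loopback
#' implementation connects a controller-side endpoint `a` to a module-side
#' endpoint `b` through in-memory queues; a serial-port implementation of the
#' same contract would connect to real hardware.
#'
#' @return `list(a = , b = )`, two endpoints with `write_line`/`read_line`.
#' @export
loopback_transport <- function() {
  q_ab <- character(0)
  q_ba <- character(0)
  endpoint <- function(side) {
    list(
      write_line = function(line) {
        if (side == "a") q_ab <<- c(q_ab, line) else q_ba <<- c(q_ba, line)
        invisible(NULL)
      },
      read_line = function() {
        if (side == "a") {
          if (!length(q_ba)) return(NULL)
          out <- q_ba[1]; q_ba <<- q_ba[-1]; out
        } else {
          if (!length(q_ab)) return(NULL)
          out <- q_ab[1]; q_ab <<- q_ab[-1]; out
        }
      }
    )
  }
  list(a = endpoint("a"), b = endpoint("b"))
}

#' Virtual pump-module endpoint
#'
#' A software stand-in for the microcontroller firmware at the far end of
#' the transport: answers `IDENTIFY` with its identity, acknowledges doses
#' (recording them), serves and stores calibration. Persistence of the
#' calibration in module memory is modelled by this endpoint keeping the
#' last `SET_CAL` payload.
#'
#' @param identity a [module_identity()].
#' @return A function `handle(line) -> reply line`; its environment keeps
#'   `doses` (list of executed DOSE messages).
#' @export
pump_module_endpoint <- function(identity) {
  stopifnot(inherits(identity, "module_identity"))
  doses <- list()
  handle <- function(line) {
    msg <- tryCatch(protocol_decode(line), error = function(e)
      list(type = "ERROR", text = conditionMessage(e)))
    reply <- switch(msg$type,
      IDENTIFY = list(type = "IDENTITY", identity = identity),
      GET_CAL = list(type = "SET_CAL", calibration = identity$calibration),
      SET_CAL = { identity$calibration <<- msg$calibration
                  list(type = "ACK") },
      DOSE = { doses[[length(doses) + 1L]] <<- msg
               list(type = "ACK") },
      STOP = list(type = "ACK"),
      ERROR = msg,
      list(type = "ERROR", text = paste("unsupported:", msg$type)))
    protocol_encode(reply)
  }
  attr(handle, "get_doses") <- function() doses
  handle
}
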