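#' Inventory policy parameters for non-player chain actors
#'
#' Bundles the quantities driving the (R, Q)-style replenishment rule used by
#' the distributor and manufacturer: a target service level with its one-sided
#' normal quantile `z`, mean daily demand, replenishment lead time, and the
#' ordering/holding cost pair entering the economic order quantity.
#'
#' @param service_level Target probability of not stocking out during a
#'   replenishment cycle. Default 0.95.
#' @param z Service-level factor (standard-normal quantile matching
#'   `service_level`). Defaults to 1.645, the one-sided 95% quantile.
#' @param mean_demand Mean daily demand in units/day.
#' @param lead_time Replenishment lead time in whole days (>= 1).
#' @param order_cost Fixed cost per order placed (currency/order).
#' @param holding_cost Holding cost (currency/unit/day).
#'
#' @return An object of class `policy_params` (a validated list).
#' @export
#' @examples
#' p <- policy_params(mean_demand = 7)
#' safety_stock(p)
#' reorder_point(p)
#' eoq(p)
policy_params <- function(service_level = 0.95, z = 1.645, mean_demand = 7,
                          lead_time = 1, order_cost = 1, holding_cost = 1) {
  if (!is.numeric(service_level) || service_level <= 0 || service_level >= 1)
    abort("`service_level` must lie in (0, 1).", class = "neuroplay_parameter_error")
  if (!is.numeric(z) || z <= 0)
    abort("`z` must be a positive service-level factor.", class = "neuroplay_parameter_error")
  if (!is.numeric(mean_demand) || mean_demand < 0)
    abort("`mean_demand` must be non-negative.", class = "neuroplay_parameter_error")
  if (!is.numeric(lead_time) || lead_time < 1 || lead_time != round(lead_time))
    abort("`lead_time` must be a whole number of days >= 1.", class = "neuroplay_parameter_error")
  if (!is.numeric(order_cost) || order_cost <= 0)
    abort("`order_cost` must be positive.", class = "neuroplay_parameter_error")
  if (!is.numeric(holding_cost) || holding_cost <= 0)
    abort("`holding_cost` must be positive.", class = "neuroplay_parameter_error")
  structure(
    list(service_level = service_level, z = z, mean_demand = mean_demand,
         lead_time = as.integer(lead_time), order_cost = order_cost,
         holding_cost = holding_cost),
    class = "policy_params"
  )
}

#' Safety stock, reorder point and economic order quantity
#'
#' The replenishment rule used by the chain's computer-controlled actors.
#' Safety stock is `z * mean_demand * lead_time` (the game's linearised buffer
#' rule; note this deliberately omits the demand standard deviation and the
#' square root of lead time of the classical textbook formula — see the
#' methods vignette). The reorder point adds expected lead-time demand, and
#' the order quantity is the classical EOQ `sqrt(2 * D * K / h)`.
#'
#' @param params A [policy_params()] object.
#' @return A single numeric value in units.
#' @export
safety_stock <- function(params) {
  stopifnot(inherits(params, "policy_params"))
  params$z * params$mean_demand * params$lead_time
}

#' @rdname safety_stock
#' @export
reorder_point <- function(params) {
  safety_stock(params) + params$mean_demand * params$lead_time
}

#' @rdname safety_stock
#' @export
eoq <- function(params) {
  stopifnot(inherits(params, "policy_params"))
  sqrt(2 * params$mean_demand * params$order_cost / params$holding_cost)
}

#' Replenishment decision for a computer-controlled actor
#'
#' Implements the inclusive (R, Q) trigger: when the actor's inventory
#' position (on-hand plus in-transit) is at or below the reorder point, order
#' `ceiling(eoq)` units; otherwise order nothing. Only the distributor and the
#' manufacturer follow this policy — the farmer is an infinite source and the
#' customer a pure demand sink.
#'
#' @param actor An actor state as found in a [new_game()] chain, or a plain
#'   list with fields `name`, `inventory` and `in_transit`.
#' @param params A [policy_params()] object.
#' @return Integer order quantity (units).
#' @export
npc_order <- function(actor, params) {
  if (!actor$name %in% c("distributor", "manufacturer"))
    abort(paste0("Actor '", actor$name, "' does not follow the replenishment policy."),
          class = "neuroplay_policy_error")
  position <- actor$inventory + sum(actor$in_transit$units)
  if (position <= reorder_point(params)) as.integer(ceiling(eoq(params))) else 0L
}

new_actor <- function(name, inventory) {
  list(name = name, inventory = inventory,
       in_transit = tibble(arrival_day = integer(), units = numeric()),
       cum_sales = 0, cum_lost = 0, cum_demand = 0)
}

#' Scenario configuration for the supply-chain game
#'
#' Defines one play-through: the scripted customer demand (default the
#' seven-day schedule 5, 8, 12, 8, 8, 5, 3), starting inventories, the
#' communication phase, prices and the NPC replenishment policy. In the
#' communication phase upstream actors disclose their inventory and expected
#' next order to the player; disclosure is purely observational and never
#' changes how the chain evolves.
#'
#' @param demand Integer vector of daily customer demand.
#' @param start_inventory Named numeric vector with entries `retailer`,
#'   `distributor`, `manufacturer` (the farmer holds infinite stock).
#' @param phase `"no_communication"` or `"communication"`.
#' @param unit_price Sale price per unit at the retailer (currency/unit).
#' @param holding_cost Player's holding-cost rate (currency/unit/day).
#' @param lead_time Shipment lead time in days for every chain link.
#' @param npc A [policy_params()] object shared by distributor and
#'   manufacturer. Its `mean_demand` defaults to the mean of `demand`.
#'
#' @return A `game_config` list.
#' @export
game_config <- function(demand = c(5, 8, 12, 8, 8, 5, 3),
                        start_inventory = c(retailer = 10, distributor = 20,
                                            manufacturer = 20),
                        phase = c("no_communication", "communication"),
                        unit_price = 1, holding_cost = 1, lead_time = 1,
                        npc = NULL) {
  phase <- match.arg(phase)
  if (!is.numeric(demand) || length(demand) < 1 || any(demand < 0) ||
      any(demand != round(demand)))
    abort("`demand` must be a vector of non-negative integers.",
          class = "neuroplay_config_error")
  need <- c("retailer", "distributor", "manufacturer")
  if (!all(need %in% names(start_inventory)) || any(start_inventory[need] < 0))
    abort("`start_inventory` needs non-negative retailer/distributor/manufacturer entries.",
          class = "neuroplay_config_error")
  if (!is.numeric(lead_time) || lead_time < 1 || lead_time != round(lead_time))
    abort("`lead_time` must be a whole number of days >= 1.",
          class = "neuroplay_config_error")
  npc <- npc %||% policy_params(mean_demand = mean(demand),
                                lead_time = as.integer(lead_time))
  structure(
    list(demand = as.integer(demand), start_inventory = start_inventory[need],
         phase = phase, unit_price = unit_price, holding_cost = holding_cost,
         lead_time = as.integer(lead_time), npc = npc),
    class = "game_config"
  )
}

#' Initialise a fresh chain state from a scenario configuration
#'
#' @param config A [game_config()] object.
#' @return A `chain_state` list with day counter, phase, actor states
#'   (farmer -> manufacturer -> distributor -> retailer; the customer is the
#'   scripted demand source) and an empty day ledger.
#' @export
new_game <- function(config) {
  stopifnot(inherits(config, "game_config"))
  structure(
    list(day = 1L, phase = config$phase, config = config,
         actors = list(
           retailer = new_actor("retailer", config$start_inventory[["retailer"]]),
           distributor = new_actor("distributor", config$start_inventory[["distributor"]]),
           manufacturer = new_actor("manufacturer", config$start_inventory[["manufacturer"]]),
           farmer = new_actor("farmer", Inf)
         ),
         records = list()),
    class = "chain_state"
  )
}

receive_arrivals <- function(actor, day) {
  due <- actor$in_transit$arrival_day <= day
  arrived <- sum(actor$in_transit$units[due])
  actor$in_transit <- actor$in_transit[!due, ]
  actor$inventory <- actor$inventory + arrived
  list(actor = actor, arrived = arrived)
}

fulfil <- function(actor, demand) {
  sales <- min(demand, actor$inventory)
  actor$inventory <- actor$inventory - sales
  actor$cum_sales <- actor$cum_sales + sales
  actor$cum_lost <- actor$cum_lost + (demand - sales)
  actor$cum_demand <- actor$cum_demand + demand
  list(actor = actor, sales = sales, lost = demand - sales)
}

#' Advance the supply chain by one simulated day
#'
#' Within a day, each actor (downstream to upstream) first receives shipments
#' due today, then fulfils its demand — scripted customer demand for the
#' retailer, the downstream order for everyone else — recording sales and lost
#' sales, then places its own order (the player's order for the retailer, the
#' replenishment policy for distributor and manufacturer; the farmer always
#' ships in full). Shipped units enter the downstream actor's in-transit
#' pipeline and arrive after the configured lead time. Unmet demand is lost,
#' never backordered.
#'
#' @param state A `chain_state` from [new_game()] or a previous step.
#' @param player_order Non-negative integer: units the player (retailer)
#'   orders from the distributor today.
#' @return A list with the advanced `state` and the day's ledger `record`
#'   (a tibble, one row per actor).
#' @export
step_day <- function(state, player_order) {
  stopifnot(inherits(state, "chain_state"))
  cfg <- state$config
  d <- state$day
  if (d > length(cfg$demand))
    abort("The demand schedule is exhausted: scenario complete.",
          class = "neuroplay_scenario_complete")
  if (!is.numeric(player_order) || length(player_order) != 1 ||
      player_order < 0 || player_order != round(player_order))
    abort("`player_order` must be a single non-negative integer.",
          class = "neuroplay_parameter_error")
  a <- state$actors
  start_inv <- vapply(a, function(x) x$inventory, numeric(1))
  arrived <- list()
  for (nm in names(a)) {
    r <- receive_arrivals(a[[nm]], d)
    a[[nm]] <- r$actor
    arrived[[nm]] <- r$arrived
  }

  # demand cascades downstream -> upstream within the day
  demand <- c(retailer = cfg$demand[d])
  f <- fulfil(a$retailer, demand[["retailer"]])
  a$retailer <- f$actor
  res <- list(retailer = f)
  orders <- c(retailer = as.numeric(player_order))

  demand[["distributor"]] <- orders[["retailer"]]
  f <- fulfil(a$distributor, demand[["distributor"]])
  a$distributor <- f$actor
  res$distributor <- f
  if (f$sales > 0)
    a$retailer$in_transit <- bind_rows(
      a$retailer$in_transit,
      tibble(arrival_day = d + cfg$lead_time, units = f$sales))
  orders[["distributor"]] <- npc_order(a$distributor, cfg$npc)

  demand[["manufacturer"]] <- orders[["distributor"]]
  f <- fulfil(a$manufacturer, demand[["manufacturer"]])
  a$manufacturer <- f$actor
  res$manufacturer <- f
  if (f$sales > 0)
    a$distributor$in_transit <- bind_rows(
      a$distributor$in_transit,
      tibble(arrival_day = d + cfg$lead_time, units = f$sales))
  orders[["manufacturer"]] <- npc_order(a$manufacturer, cfg$npc)

  demand[["farmer"]] <- orders[["manufacturer"]]
  f <- fulfil(a$farmer, demand[["farmer"]])   # infinite stock: ships in full
  a$farmer <- f$actor
  res$farmer <- f
  if (f$sales > 0)
    a$manufacturer$in_transit <- bind_rows(
      a$manufacturer$in_transit,
      tibble(arrival_day = d + cfg$lead_time, units = f$sales))
  orders[["farmer"]] <- 0

  nms <- names(a)
  record <- tibble(
    day = d, actor = nms,
    demand_faced = as.numeric(demand[nms]),
    sales = unname(vapply(res[nms], function(x) x$sales, numeric(1))),
    lost_sales = unname(vapply(res[nms], function(x) x$lost, numeric(1))),
    order_placed = as.numeric(orders[nms]),
    arrivals = as.numeric(unlist(arrived[nms])),
    start_inventory = as.numeric(start_inv[nms]),
    end_inventory = unname(vapply(a[nms], function(x) x$inventory, numeric(1))),
    revenue = ifelse(nms == "retailer", res$retailer$sales * cfg$unit_price, NA_real_),
    holding_cost_incurred = ifelse(nms == "retailer",
                                   a$retailer$inventory * cfg$holding_cost,
                                   NA_real_),
    phase = cfg$phase,
    disclosed_inventory = if (cfg$phase == "communication")
      ifelse(nms %in% c("distributor", "manufacturer"),
             unname(vapply(a[nms], function(x) x$inventory, numeric(1))),
             NA_real_)
      else NA_real_,
    disclosed_expected_order = if (cfg$phase == "communication")
      ifelse(nms %in% c("distributor", "manufacturer"),
             as.numeric(orders[nms]), NA_real_)
      else NA_real_
  )
  state$actors <- a
  state$day <- d + 1L
  state$records <- c(state$records, list(record))
  list(state = state, record = record)
}

#' Run a full scenario and aggregate player KPIs
#'
#' @param config A [game_config()] object.
#' @param player_policy Either `NULL` (the default "chase" policy: order
#'   exactly today's customer demand), a numeric vector of daily orders (one
#'   per scheduled day), or a function `f(day, view)` returning the day's
#'   order; `view` carries the retailer's inventory and, in the communication
#'   phase, the upstream actors' inventories and expected orders.
#' @return A list with `ledger` (tibble of all day records) and `kpis`
#'   (a [kpi_report()] tibble).
#' @export
run_scenario <- function(config, player_policy = NULL) {
  stopifnot(inherits(config, "game_config"))
  n_days <- length(config$demand)
  if (is.numeric(player_policy) && length(player_policy) != n_days)
    abort("A fixed order list must supply one order per scheduled day.",
          class = "neuroplay_config_error")
  state <- new_game(config)
  for (d in seq_len(n_days)) {
    ord <- if (is.null(player_policy)) {
      config$demand[d]
    } else if (is.numeric(player_policy)) {
      player_policy[d]
    } else {
      view <- list(day = d, retailer_inventory = state$actors$retailer$inventory)
      if (config$phase == "communication") {
        view$upstream_inventory <- c(
          distributor = state$actors$distributor$inventory,
          manufacturer = state$actors$manufacturer$inventory)
        view$upstream_expected_order <- c(
          distributor = tryCatch(npc_order(state$actors$distributor, config$npc),
                                 error = function(e) NA_integer_),
          manufacturer = tryCatch(npc_order(state$actors$manufacturer, config$npc),
                                  error = function(e) NA_integer_))
      }
      player_policy(d, view)
    }
    state <- step_day(state, ord)$state
  }
  ledger <- bind_rows(state$records)
  list(ledger = ledger, kpis = kpi_report(ledger, config))
}

#' Bullwhip ratio of an order stream against customer demand
#'
#' The classical variance-amplification measure: population variance of the
#' orders an actor places divided by the population variance of end-customer
#' demand. Values above 1 indicate the actor amplifies demand variability.
#'
#' @param orders,demand Numeric series of equal length (>= 2).
#' @return A single non-negative number.
#' @export
bullwhip_ratio <- function(orders, demand) {
  if (length(orders) != length(demand) || length(orders) < 2)
    abort("`orders` and `demand` must have equal length >= 2.",
          class = "neuroplay_parameter_error")
  pvar <- function(x) mean((x - mean(x))^2)
  vd <- pvar(demand)
  if (vd == 0)
    abort("Demand variance is zero: bullwhip ratio undefined.",
          class = "neuroplay_undefined_ratio_error")
  pvar(orders) / vd
}

#' KPI summary of a finished game ledger
#'
#' Totals the player's revenue, lost sales and holding cost over the run and
#' attaches each actor's bullwhip ratio against customer demand.
#'
#' @param ledger A day ledger as returned by [run_scenario()].
#' @param config The [game_config()] that produced it.
#' @return A tibble with one row per actor plus the player totals repeated on
#'   the retailer row.
#' @export
kpi_report <- function(ledger, config) {
  customer_demand <- ledger$demand_faced[ledger$actor == "retailer"]
  retailer <- ledger[ledger$actor == "retailer", ]
  per_actor <- ledger |>
    group_by(.data$actor) |>
    summarise(
      total_orders = sum(.data$order_placed),
      total_lost_sales = sum(.data$lost_sales),
      bullwhip = tryCatch(
        bullwhip_ratio(.data$order_placed, customer_demand),
        error = function(e) NA_real_),
      .groups = "drop")
  per_actor$total_revenue <- ifelse(per_actor$actor == "retailer",
                                    sum(retailer$revenue), NA_real_)
  per_actor$total_holding_cost <- ifelse(per_actor$actor == "retailer",
                                         sum(retailer$holding_cost_incurred),
                                         NA_real_)
  per_actor
}
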