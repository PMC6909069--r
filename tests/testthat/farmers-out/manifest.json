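{
  "package": "farmersgame",
  "version": "0.1.0",
  "timestamp": "2026-09-20T02:35:23+0000",
  "seed": null,
  "config": {
    "payoffs": {
      "reward_cc": 1.1,
      "temptation_dc": 2.2,
      "sucker_cd": 0,
      "punish_dd": 1
    },
    "turn_cost": 1.07,
    "forgiveness": 0.1,
    "rows": 20,
    "cols": 20,
    "rounds": 50,
    "density_poor": 0.5,
    "wealth_poor": 4,
    "wealth_rich": 10,
    "subsist_threshold": 4,
    "middle_threshold": 8,
    "wealth_ratio_trigger": 2,
    "strategy_mix": {
      "titfortat": 1,
      "subsist": 1,
      "exploit": 1,
      "thief": 1,
      "middle": 1,
      "always_defect": 0
    },
    "borderless": false,
    "seed": null
  },
  "outputs": {
    "summary": "farmers-out/summary.csv",
    "series": "farmers-out/series.csv",
    "deaths": "farmers-out/deaths.csv",
    "agents": "farmers-out/agents.csv"
  }
}
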