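{
  "subprocesses": [
    {"name": "registration",         "order": 1, "mean": 14.0,  "sd": 1.9,  "servers": 16, "resource": "clerk"},
    {"name": "triage",               "order": 2, "mean": 17.0,  "sd": 3.7,  "servers": 24, "resource": "nurse"},
    {"name": "assessment",           "order": 3, "mean": 14.2,  "sd": 4.5,  "servers": 22, "resource": "ED physician"},
    {"name": "referral_to_medicine", "order": 4, "mean": 175.3, "sd": 38.1, "servers": 1,  "resource": "medical registrar"},
    {"name": "decision_to_admit",    "order": 5, "mean": 525.5, "sd": 93.5, "servers": 2,  "resource": "medical registrar"},
    {"name": "room_allocation",      "order": 6, "mean": 163.6, "sd": 28.8, "servers": 2,  "resource": "nurse"},
    {"name": "physical_transfer",    "order": 7, "mean": 66.4,  "sd": 12.2, "servers": 3,  "resource": "nurse"}
  ],
  "arrivals": {
    "funnel_mean_interarrival_min": 5.78,
    "admitted_per_day": 52
  },
  "annual_funnel": {
    "ed_visits": 386889,
    "referrals": 30185,
    "admissions": 19058
  },
  "daily_admissions": {
    "mean": 52, "sd": 28, "min": 28, "max": 79
  },
  "monthly_admissions": {
    "median": 955, "min": 707, "max": 1331
  },
  "ed_boarding_capacity": 250,
  "bed_pools": [
    {"pool": "ward", "beds": 173, "share": 0.45, "los_hours": 72},
    {"pool": "AAU",  "beds": 24,  "share": 0.35, "los_hours": 24},
    {"pool": "AMAU", "beds": 51,  "share": 0.20, "los_hours": 48}
  ],
  "shifts": {"shifts_per_day": 3, "shift_length_min": 480},
  "queue_cap": 1000000,
  "six_hour_target_min": 360
}
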