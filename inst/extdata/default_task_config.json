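{
  "task1": {
    "Q1": {
      "reward_prob": [
        [0.8, 0.2, 0.2],
        [0.2, 0.8, 0.2],
        [0.2, 0.2, 0.8]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 2000
    },
    "Q2": {
      "reward_prob": [
        [0.8, 0.2, 0.2],
        [0.2, 0.8, 0.2],
        [0.2, 0.2, 0.8]
      ],
      "state_counts": [90, 30, 30],
      "deadline_ms": 2000
    }
  },
  "task2": {
    "Q1": {
      "reward_prob": [
        [1, 0, 0],
        [0, 1, 0],
        [0, 0, 1]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 2000
    },
    "Q2": {
      "reward_prob": [
        [1, 0, 0],
        [1, 1, 0],
        [1, 0, 1]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 2000
    }
  },
  "task3": {
    "Q1": {
      "reward_prob": [
        [1, 0.25, 0],
        [1, 0.25, 0],
        [0.25, 0, 1]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 2000
    },
    "Q2": {
      "reward_prob": [
        [1, 0.25, 0],
        [1, 0.25, 0],
        [0.25, 0, 1]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 1000
    }
  },
  "demo": {
    "Q1": {
      "reward_prob": [
        [1, 0, 0],
        [1, 0, 0],
        [0, 0, 1]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 2000
    },
    "Q2": {
      "reward_prob": [
        [1, 0, 0],
        [1, 0, 0],
        [0, 0, 1]
      ],
      "state_counts": [30, 30, 30],
      "deadline_ms": 2000
    }
  }
}
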