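{
  "meta": {
    "description": "Decision table: which EGR1/COX-2/IL-8 expression codes identify which input-signal combinations (TNFa pattern x temperature).",
    "genes": {"E": "EGR1", "C": "COX-2 (PTGS2)", "I": "IL-8 (CXCL-8)"},
    "symbols": {"+": "high expression at the stated time", "-": "low expression at the stated time", "+130": "high expression at 130 minutes"},
    "observation_times_min": [30, 130],
    "provenance": {
      "caption_constraints": "6 conditions; 5 distinguishable classes from t=30 codes (unstimulated plus four stimulated combinations), one further condition separated only when t=130 codes are added; E+I- at 30 min uniquely identifies 5-minute pulses at 37C",
      "cells": "transcribed-from-figure:reconstructed - individual cells not quotable from the caption were reconstructed to satisfy the caption constraints and are synthetic stand-ins"
    }
  },
  "conditions": [
    {"label": "unstimulated, 37C", "pattern": "unstimulated", "temperature": 37,
     "code": {"E30": "-", "C30": "-", "I30": "-", "E130": "-", "C130": "-", "I130": "-"}},
    {"label": "continuous TNFa, 37C", "pattern": "continuous", "temperature": 37,
     "code": {"E30": "+", "C30": "-", "I30": "+", "E130": "-", "C130": "-", "I130": "+"}},
    {"label": "continuous TNFa, 40C", "pattern": "continuous", "temperature": 40,
     "code": {"E30": "-", "C30": "+", "I30": "+", "E130": "-", "C130": "+", "I130": "+"}},
    {"label": "5-minute pulses every 100 min, 37C", "pattern": "pulse5", "temperature": 37,
     "code": {"E30": "+", "C30": "-", "I30": "-", "E130": "+", "C130": "-", "I130": "-"}},
    {"label": "5-minute pulses every 100 min, 40C", "pattern": "pulse5", "temperature": 40,
     "code": {"E30": "-", "C30": "+", "I30": "-", "E130": "-", "C130": "+", "I130": "-"}},
    {"label": "20-minute pulses every 100 min, 37C", "pattern": "pulse20", "temperature": 37,
     "code": {"E30": "+", "C30": "-", "I30": "+", "E130": "+", "C130": "+", "I130": "-"}}
  ]
}
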