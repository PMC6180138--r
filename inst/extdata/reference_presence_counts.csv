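label,instrument,item,subscale,presence_pre,presence_post,n_participants
DASS-21: 5,DASS21,5,depression,21,22,40
DASS-21: 16,DASS21,16,depression,16,15,40
DASS-21: 9,DASS21,9,anxiety,19,17,40
DASS-21: 6,DASS21,6,stress,27,23,40
DASS-21: 11,DASS21,11,stress,22,23,40
DASS-21: 12,DASS21,12,stress,26,23,40
DASS-21: 14,DASS21,14,stress,22,19,40
EQ-short: 2,EQ_SHORT,2,empathy,21,22,40
EQ-short: 4,EQ_SHORT,4,empathy,16,21,40
EQ-short: 5,EQ_SHORT,5,empathy,20,24,40
EQ-short: 7,EQ_SHORT,7,empathy,20,24,40
EQ-short: 8,EQ_SHORT,8,empathy,16,22,40
EQ-short: 9,EQ_SHORT,9,empathy,22,25,40
JSE-S: 6,JSE_S,6,empathy,20,14,40
EES: 2,EES,2,expressivity,18,16,40
EES: 3,EES,3,expressivity,17,15,40
EES: 4,EES,4,expressivity,16,14,40
EES: 9,EES,9,expressivity,18,21,40
EES: 10,EES,10,expressivity,14,16,40
EES: 11,EES,11,expressivity,18,16,40
EES: 12,EES,12,expressivity,17,17,40
EES: 13,EES,13,expressivity,22,25,40
EES: 14,EES,14,expressivity,14,16,40
EES: 15,EES,15,expressivity,20,15,40
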