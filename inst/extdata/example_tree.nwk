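(((t1:0.601731867644,t7:0.601731867644):0.312823383121,t6:0.914555250765):2.08544474923,((t3:0.176049766623,(t8:0.160234954199,t9:0.160234954199):0.015814812424):2.31317431641,t5:2.48922408304):0.510775916963);
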