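name,n_items,item_min,item_max,reverse_items,notes
PCS,13,0,4,,pain catastrophizing scale; sum 0-52
STAI-T,20,1,4,1;4;6;7;10;13;14;16;19,trait anxiety; anxiety-absent items reverse-keyed; sum 20-80
FFMQ4,32,1,5,1;2;3;4;5;6;7;8;17;18;19;20;21;22;23;24,four-facet mindfulness (observing facet excluded); items ordered act-aware (1-8; reverse) / describe (9-16) / nonjudge (17-24; reverse) / nonreact (25-32); sum 32-160
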