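species	cluster	members
drerio	dre-cluster-17-92	17a-1,18a,19a,20a,19b,92a-1
drerio	dre-cluster-18c	18c,20b,19c,363
drerio	dre-cluster-462	462,731
drerio	dre-cluster-222	222a,221
drerio	dre-cluster-93	93,19d,25
drerio	dre-cluster-194	194a,192
drerio	dre-cluster-183	183,96,182
drerio	dre-cluster-144	144,451
drerio	dre-cluster-212	212,132-1
drerio	dre-cluster-23a	23a-1,27e,24-4
drerio	dre-cluster-430	430a-18,430c-1,430b-4
drerio	dre-cluster-130	130c-1,301c
drerio	dre-cluster-99	99-1,let-7c-1,125c
drerio	dre-cluster-let7e	let-7e,let-7a-5
drerio	dre-cluster-let7a	let-7a-1,let-7f
drerio	dre-cluster-let7g	let-7g-2,let-7h
drerio	dre-cluster-30	30d,30b
drerio	dre-cluster-100	100-1,let-7a-2,125b-1
drerio	dre-cluster-15	15a-1,16b
drerio	dre-cluster-199	199-1,214
drerio	dre-cluster-29	29b-2,29a
drerio	dre-cluster-200	200b,200a,429a
drerio	dre-cluster-1	1-2,133a-1
drerio	dre-cluster-143	143-1,145
drerio	dre-cluster-181	181a-2,181b-2
drerio	dre-cluster-193	193a-1,365-2
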