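wavelength_nm	epsilon
450	1
451	0.95574
452	0.913447
453	0.873033
454	0.834415
455	0.797513
456	0.762251
457	0.728556
458	0.696358
459	0.665591
460	0.636192
461	0.608098
462	0.581253
463	0.555601
464	0.531089
465	0.507666
466	0.485284
467	0.463896
468	0.443459
469	0.42393
470	0.405269
471	0.387437
472	0.370398
473	0.354116
474	0.338557
475	0.323689
476	0.309483
477	0.295907
478	0.282935
479	0.270539
480	0.258694
481	0.247376
482	0.23656
483	0.226225
484	0.21635
485	0.206913
486	0.197895
487	0.189278
488	0.181044
489	0.173176
490	0.165658
491	0.158474
492	0.151609
493	0.145049
494	0.13878
495	0.13279
496	0.127066
497	0.121597
498	0.116371
499	0.111377
500	0.106604
501	0.102044
502	0.0976868
503	0.093523
504	0.0895443
505	0.0857425
506	0.0821098
507	0.0786391
508	0.0753236
509	0.0721571
510	0.0691344
511	0.0662518
512	0.0635073
513	0.0609019
514	0.0584411
515	0.0561371
516	0.0540115
517	0.0520999
518	0.0504562
519	0.0491597
520	0.0483215
521	0.0480921
522	0.0486682
523	0.0502971
524	0.0532783
525	0.0579584
526	0.0647186
527	0.0739533
528	0.0860376
529	0.101286
530	0.119901
531	0.141924
532	0.167184
533	0.195254
534	0.225437
535	0.256763
536	0.288024
537	0.31784
538	0.344751
539	0.367326
540	0.384287
541	0.394621
542	0.39768
543	0.393238
544	0.381518
545	0.363166
546	0.339192
547	0.310872
548	0.279635
549	0.246942
550	0.214174
551	0.182545
552	0.153035
553	0.126365
554	0.102996
555	0.0831567
556	0.0668954
557	0.0541376
558	0.0447518
559	0.0386094
560	0.0356351
561	0.0358406
562	0.0393386
563	0.0463324
564	0.0570812
565	0.0718414
566	0.0907881
567	0.113925
568	0.140997
569	0.171413
570	0.204209
571	0.238044
572	0.271267
573	0.302021
574	0.328408
575	0.348674
576	0.361397
577	0.36565
578	0.361112
579	0.348103
580	0.327547
581	0.300862
582	0.269799
583	0.236249
584	0.202054
585	0.168851
586	0.137951
587	0.110279
588	0.0863658
589	0.0663825
590	0.0502093
591	0.0375161
592	0.0278455
593	0.0206864
594	0.0155319
595	0.0119187
596	0.00944982
597	0.0078024
598	0.00672618
599	0.00603509
600	0.00559611
601	0.00531759
602	0.00513853
603	0.00501968
604	0.00493656
605	0.00487439
606	0.00482449
607	0.00478189
608	0.00474384
609	0.00470883
610	0.00467603
611	0.00464502
612	0.00461552
613	0.00458741
614	0.00456058
615	0.00453495
616	0.00451047
617	0.00448707
618	0.00446472
619	0.00444336
620	0.00442295
621	0.00440345
622	0.00438481
623	0.00436701
624	0.00434999
625	0.00433373
626	0.00431819
627	0.00430334
628	0.00428915
629	0.0042756
630	0.00426264
631	0.00425026
632	0.00423843
633	0.00422713
634	0.00421633
635	0.00420601
636	0.00419615
637	0.00418672
638	0.00417772
639	0.00416911
640	0.00416089
641	0.00415303
642	0.00414552
643	0.00413835
644	0.00413149
645	0.00412494
646	0.00411868
647	0.0041127
648	0.00410698
649	0.00410152
650	0.0040963
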