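wavelength_nm	epsilon
450	0.992231
451	0.993705
452	0.995062
453	0.996287
454	0.997365
455	0.998281
456	0.999019
457	0.999562
458	0.999895
459	1
460	0.999861
461	0.999461
462	0.998782
463	0.997807
464	0.996518
465	0.994897
466	0.992926
467	0.990588
468	0.987862
469	0.984732
470	0.98118
471	0.977185
472	0.97273
473	0.967797
474	0.962366
475	0.95642
476	0.94994
477	0.942908
478	0.935307
479	0.92712
480	0.918331
481	0.908924
482	0.898886
483	0.888202
484	0.876863
485	0.864858
486	0.852181
487	0.838828
488	0.824797
489	0.810091
490	0.794716
491	0.778682
492	0.762004
493	0.7447
494	0.726797
495	0.708324
496	0.689317
497	0.669815
498	0.649866
499	0.62952
500	0.608833
501	0.587865
502	0.566679
503	0.545343
504	0.523925
505	0.502495
506	0.481123
507	0.45988
508	0.438835
509	0.418054
510	0.3976
511	0.377533
512	0.357907
513	0.338772
514	0.320174
515	0.302149
516	0.284732
517	0.267948
518	0.251819
519	0.236359
520	0.221578
521	0.207479
522	0.194063
523	0.181325
524	0.169255
525	0.157842
526	0.14707
527	0.136922
528	0.127377
529	0.118415
530	0.110012
531	0.102144
532	0.0947888
533	0.0879201
534	0.0815138
535	0.0755452
536	0.0699904
537	0.0648255
538	0.0600276
539	0.0555744
540	0.0514444
541	0.0476168
542	0.0440721
543	0.0407912
544	0.0377565
545	0.0349509
546	0.0323584
547	0.0299639
548	0.0277533
549	0.0257132
550	0.0238312
551	0.0220956
552	0.0204954
553	0.0190206
554	0.0176615
555	0.0164095
556	0.0152563
557	0.0141943
558	0.0132165
559	0.0123163
560	0.0114877
561	0.010725
562	0.0100232
563	0.00937732
564	0.00878304
565	0.00823626
566	0.0077332
567	0.0072704
568	0.00684466
569	0.00645301
570	0.00609273
571	0.00576133
572	0.00545649
573	0.00517608
574	0.00491815
575	0.0046809
576	0.00446267
577	0.00426194
578	0.00407729
579	0.00390745
580	0.00375122
581	0.00360751
582	0.00347532
583	0.00335372
584	0.00324186
585	0.00313897
586	0.00304431
587	0.00295724
588	0.00287714
589	0.00280345
590	0.00273566
591	0.0026733
592	0.00261592
593	0.00256314
594	0.00251459
595	0.00246992
596	0.00242882
597	0.00239101
598	0.00235623
599	0.00232423
600	0.00229479
601	0.0022677
602	0.00224278
603	0.00221985
604	0.00219876
605	0.00217935
606	0.0021615
607	0.00214507
608	0.00212995
609	0.00211605
610	0.00210326
611	0.00209149
612	0.00208066
613	0.00207069
614	0.00206153
615	0.00205309
616	0.00204533
617	0.00203819
618	0.00203162
619	0.00202558
620	0.00202002
621	0.00201491
622	0.0020102
623	0.00200587
624	0.00200188
625	0.00199822
626	0.00199485
627	0.00199174
628	0.00198889
629	0.00198626
630	0.00198385
631	0.00198162
632	0.00197958
633	0.0019777
634	0.00197596
635	0.00197437
636	0.00197291
637	0.00197156
638	0.00197032
639	0.00196917
640	0.00196812
641	0.00196716
642	0.00196627
643	0.00196545
644	0.0019647
645	0.00196401
646	0.00196337
647	0.00196278
648	0.00196224
649	0.00196175
650	0.00196129
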